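# Elastic electron scattering amplitudes.
#
# Parametrization: 5-Gaussian fits of Peng, Ren, Dudarev & Whelan,
# Acta Cryst. A52, 257 (1996), table for neutral atoms:
#   f(s) = sum_i a_i * exp(-b_i * g^2),  g = s / (4*pi)  [A^-1, Bragg variable]
# with s the momentum-transfer magnitude s = (4*pi/lambda) sin(theta/2).
# Amplitudes are in Angstrom. f(0) sums: H 0.529, C 2.509, O 1.983 A.

.peng_coefficients <- list(
  H = list(a = c(0.0349, 0.1201, 0.1970, 0.0573, 0.1195),
           b = c(0.5347, 3.5867, 12.3471, 18.9525, 38.6269)),
  C = list(a = c(0.0893, 0.2563, 0.7570, 1.0487, 0.3575),
           b = c(0.2465, 1.7100, 6.4094, 18.6113, 50.2523)),
  O = list(a = c(0.0974, 0.2921, 0.6910, 0.6990, 0.2039),
           b = c(0.2067, 1.3815, 4.6943, 12.7105, 32.4726))
)

#' Elastic electron scattering-factor table
#'
#' Builds the per-element amplitude registry used by all scattering
#' calculations. Amplitude magnitudes \eqn{|f(s)|} come from the embedded
#' 5-Gaussian parametrization (H, C, O by default); scattering phases
#' \eqn{\eta(s)} default to zero, which is an excellent approximation for
#' light elements at ~100 kV but is kept as an explicit slot so the full
#' interference term \eqn{\cos(\eta_i - \eta_j)} is honoured when phases are
#' supplied.
#'
#' @param elements Character vector of element symbols to include. All must
#'   be present in the embedded coefficient table unless custom coefficients
#'   are supplied via \code{extra}.
#' @param extra Optional named list of additional elements, each a list with
#'   numeric vectors \code{a} and \code{b} (Gaussian amplitudes and widths in
#'   the Bragg-variable convention) and optionally a phase function
#'   \code{eta(s)} in radians.
#' @return An object of class \code{scattering_table}.
#' @examples
#' tab <- scattering_table()
#' scattering_amplitude(tab, "C", c(0, 5, 10))
#' @export
scattering_table <- function(elements = c("H", "C", "O"), extra = NULL) {
  coefs <- .peng_coefficients
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    coefs[names(extra)] <- lapply(extra, function(e) list(a = e$a, b = e$b))
  }
  missing <- setdiff(elements, names(coefs))
  if (length(missing))
    stop("no scattering coefficients for element(s): ",
         paste(missing, collapse = ", "))
  phases <- lapply(elements, function(el) {
    if (!is.null(extra[[el]]$eta)) extra[[el]]$eta else NULL
  })
  names(phases) <- elements
  structure(list(coefficients = coefs[elements], phases = phases),
            class = "scattering_table")
}

#' @export
print.scattering_table <- function(x, ...) {
  cat("<scattering_table> elements:", paste(names(x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

#' Query whether an element is tabulated
#' @param table A \code{scattering_table}.
#' @param element Element symbol(s).
#' @return Logical vector.
#' @export
has_element <- function(table, element) {
  stopifnot(inherits(table, "scattering_table"))
  element %in% names(table$coefficients)
}

#' Elastic scattering amplitude magnitude |f(s)|
#'
#' @param table A \code{scattering_table}.
#' @param element A single element symbol.
#' @param s Scattering-vector values in inverse Angstrom,
#'   \eqn{s = (4\pi/\lambda)\sin(\theta/2)}.
#' @return Numeric vector of amplitudes in Angstrom, strictly positive.
#' @export
scattering_amplitude <- function(table, element, s) {
  stopifnot(inherits(table, "scattering_table"), length(element) == 1L)
  co <- table$coefficients[[element]]
  if (is.null(co)) stop("element not tabulated: ", element)
  g2 <- (s / (4 * pi))^2
  f <- numeric(length(s))
  for (i in seq_along(co$a)) f <- f + co$a[i] * exp(-co$b[i] * g2)
  f
}

#' Scattering phase eta(s)
#'
#' @inheritParams scattering_amplitude
#' @return Numeric vector of phases in radians (zero unless the table was
#'   built with explicit phase functions).
#' @export
scattering_phase <- function(table, element, s) {
  stopifnot(inherits(table, "scattering_table"))
  eta <- table$phases[[element]]
  if (is.null(eta)) rep(0, length(s)) else eta(s)
}

# amplitude matrix: one row per atom of `elements`, one column per s value
.amplitude_matrix <- function(table, elements, s) {
  uel <- unique(elements)
  fs <- lapply(uel, function(el) scattering_amplitude(table, el, s))
  names(fs) <- uel
  do.call(rbind, fs)[match(elements, uel), , drop = FALSE]
}

.phase_matrix <- function(table, elements, s) {
  uel <- unique(elements)
  ps <- lapply(uel, function(el) scattering_phase(table, el, s))
  names(ps) <- uel
  do.call(rbind, ps)[match(elements, uel), , drop = FALSE]
}
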