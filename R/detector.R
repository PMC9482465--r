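# Forward detector model: map 1D curves to isotropic 2D count images with
# Poisson noise, and reduce images back to 1D by azimuthal (radial)
# averaging. Flat detector in the small-angle regime; no solid-angle
# correction (sub-1% at <= 10 A^-1 and 100 kV).

#' Detector geometry
#'
#' @param n_pixels Integer vector (rows, cols); default 1024 x 1024.
#' @param pixel_pitch Pixel size in mm. The default, with the default
#'   camera length and voltage, puts the largest fully sampled annulus at
#'   ~9.98 inverse Angstrom, just inside the default simulation grid.
#' @param camera_length Sample-to-detector distance in mm.
#' @param accel_voltage Accelerating voltage in kV (sets the wavelength of
#'   the pixel-to-s mapping).
#' @param beam_center (row, col) of the unscattered beam in pixel units, may
#'   be fractional; defaults to the image center.
#' @return Object of class \code{detector_geometry}. The defaults map the
#'   full grid of \code{s_grid()} onto the detector (edge at ~10.4 A^-1).
#' @export
detector_geometry <- function(n_pixels = c(1024L, 1024L), pixel_pitch = 0.0575,
                              camera_length = 500, accel_voltage = 100,
                              beam_center = NULL) {
  n_pixels <- as.integer(n_pixels)
  stopifnot(length(n_pixels) == 2L, all(n_pixels > 0L),
            pixel_pitch > 0, camera_length > 0)
  if (is.null(beam_center)) beam_center <- (n_pixels + 1) / 2
  if (beam_center[1L] < 1 || beam_center[1L] > n_pixels[1L] ||
      beam_center[2L] < 1 || beam_center[2L] > n_pixels[2L])
    stop("beam_center outside image bounds")
  structure(list(n_pixels = n_pixels, pixel_pitch = pixel_pitch,
                 camera_length = camera_length,
                 accel_voltage = accel_voltage,
                 wavelength = electron_wavelength(accel_voltage),
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %dx%d px, pitch %g mm, L %g mm, %g kV, center (%.2f, %.2f)\n",
              x$n_pixels[1L], x$n_pixels[2L], x$pixel_pitch, x$camera_length,
              x$accel_voltage, x$beam_center[1L], x$beam_center[2L]))
  invisible(x)
}

#' Scattering vector of a detector pixel
#'
#' Radial pixel distance -> scattering angle \eqn{\theta = \arctan(r/L)} ->
#' \eqn{s = (4\pi/\lambda)\sin(\theta/2)}. Exactly zero at the beam center.
#'
#' @param geometry A \code{detector_geometry}.
#' @param row,col Pixel coordinates (vectors of equal length, possibly
#'   fractional).
#' @return s in inverse Angstrom.
#' @export
s_of_pixel <- function(geometry, row, col) {
  stopifnot(inherits(geometry, "detector_geometry"))
  r_mm <- sqrt((row - geometry$beam_center[1L])^2 +
                 (col - geometry$beam_center[2L])^2) * geometry$pixel_pitch
  theta <- atan(r_mm / geometry$camera_length)
  (4 * pi / geometry$wavelength) * sin(theta / 2)
}

# s value of every pixel, as a matrix matching the image layout
.pixel_s_matrix <- function(geometry, beam_center = geometry$beam_center) {
  nr <- geometry$n_pixels[1L]; nc <- geometry$n_pixels[2L]
  dr2 <- (seq_len(nr) - beam_center[1L])^2
  dc2 <- (seq_len(nc) - beam_center[2L])^2
  r_mm <- sqrt(outer(dr2, dc2, "+")) * geometry$pixel_pitch
  theta <- atan(r_mm / geometry$camera_length)
  (4 * pi / geometry$wavelength) * sin(theta / 2)
}

#' Detector image container
#'
#' @param counts Numeric matrix of counts (integer after Poisson sampling,
#'   real for expectation images), non-negative where usable.
#' @param geometry A \code{detector_geometry} with matching \code{n_pixels}.
#' @param mask Logical matrix, \code{TRUE} = usable pixel; default all.
#' @param meta Optional provenance list (seed, total counts, ...).
#' @return Object of class \code{detector_image}.
#' @export
detector_image <- function(counts, geometry, mask = NULL, meta = list()) {
  counts <- as.matrix(counts)
  stopifnot(inherits(geometry, "detector_geometry"),
            all(dim(counts) == geometry$n_pixels))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(counts), ncol(counts))
  stopifnot(is.logical(mask), all(dim(mask) == dim(counts)))
  if (any(counts[mask] < 0)) stop("negative counts in usable pixels")
  structure(list(counts = counts, geometry = geometry, mask = mask,
                 meta = meta),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> %dx%d, sum %.4g counts, %d masked px\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts[x$mask]),
              sum(!x$mask)))
  invisible(x)
}

#' Render a 1D curve as an isotropic 2D detector image
#'
#' Expected value at each pixel is the curve linearly interpolated at the
#' pixel's s, normalized so the masked sum of expectations equals
#' \code{total_counts} (with \code{total_counts = NULL} the curve values are
#' used directly as per-pixel expectations, preserving the curve's absolute
#' scale). With a seed, each pixel is drawn independently from a Poisson law
#' with that expectation; \code{seed = NULL} returns the noiseless
#' expectation image.
#'
#' @param curve A \code{diffraction_curve} covering the detector's s range.
#' @param geometry A \code{detector_geometry}.
#' @param total_counts Expected total electron count over usable pixels, or
#'   \code{NULL} to render the curve on its own scale.
#' @param seed Integer seed for the Poisson draw, or \code{NULL}.
#' @param beam_stop_px Radius (pixels) of a central circular mask emulating a
#'   beam stop; 0 (default) disables it.
#' @return A \code{detector_image}.
#' @export
render_image <- function(curve, geometry, total_counts, seed = NULL,
                         beam_stop_px = 0) {
  stopifnot(inherits(curve, "diffraction_curve"),
            inherits(geometry, "detector_geometry"),
            is.null(total_counts) || total_counts > 0)
  S <- .pixel_s_matrix(geometry)
  # the curve must cover the inscribed circle (the fully sampled annuli);
  # corner pixels beyond the curve's range are masked out, not extrapolated
  edge_px <- min(geometry$beam_center[1L] - 1,
                 geometry$n_pixels[1L] - geometry$beam_center[1L],
                 geometry$beam_center[2L] - 1,
                 geometry$n_pixels[2L] - geometry$beam_center[2L])
  s_edge <- s_of_pixel(geometry, geometry$beam_center[1L] + edge_px,
                       geometry$beam_center[2L])
  if (max(curve$s) < 0.98 * s_edge)
    stop(sprintf("curve covers s <= %.3f but detector annuli extend to %.3f A^-1",
                 max(curve$s), s_edge))
  mask <- S <= max(curve$s)
  if (beam_stop_px > 0) {
    nr <- geometry$n_pixels[1L]; nc <- geometry$n_pixels[2L]
    r_px <- sqrt(outer((seq_len(nr) - geometry$beam_center[1L])^2,
                       (seq_len(nc) - geometry$beam_center[2L])^2, "+"))
    mask[r_px <= beam_stop_px] <- FALSE
  }
  expect <- matrix(stats::approx(curve$s, curve$values, xout = as.vector(S),
                                 rule = 2L)$y, nrow(S), ncol(S))
  expect[expect < 0] <- 0
  tot <- sum(expect[mask])
  if (tot <= 0 && !is.null(total_counts)) {
    if (all(curve$values == 0)) {
      # a zero curve legitimately renders to a zero image (Poisson(0) = 0)
      return(detector_image(matrix(0, nrow(S), ncol(S)), geometry, mask,
                            meta = list(total_counts = 0, seed = seed,
                                        noiseless = is.null(seed))))
    }
    stop("curve renders to zero expected intensity")
  }
  if (!is.null(total_counts)) expect <- expect * (total_counts / tot)
  expect[!mask] <- 0
  if (is.null(seed)) {
    counts <- expect
  } else {
    old_seed <- .save_rng_state()
    on.exit(.restore_rng_state(old_seed), add = TRUE)
    set.seed(as.integer(seed))
    counts <- matrix(stats::rpois(length(expect), as.vector(expect)),
                     nrow(expect), ncol(expect))
  }
  detector_image(counts, geometry, mask,
                 meta = list(total_counts = total_counts, seed = seed,
                             noiseless = is.null(seed)))
}

#' Azimuthal (radial) average of a detector image
#'
#' Mean counts per pixel in annular s bins around the beam center. Empty
#' bins are dropped and reported via the \code{empty_bins} attribute rather
#' than silently interpolated.
#'
#' @param image A \code{detector_image}.
#' @param bin_width Bin width in inverse Angstrom (default 0.02, matching the
#'   default s grid).
#' @param s_max Optional upper limit; defaults to the largest fully-sampled
#'   annulus (the inscribed-circle radius), beyond which annuli are clipped
#'   by the detector edge.
#' @return A \code{diffraction_curve} (role \code{"total"}) at bin centers,
#'   with attributes \code{n_pixels} (per bin), \code{std_error} (per bin,
#'   Poisson-agnostic sample standard error), and \code{empty_bins}.
#' @export
radial_average <- function(image, bin_width = 0.02, s_max = NULL) {
  stopifnot(inherits(image, "detector_image"), bin_width > 0)
  if (!any(image$mask)) stop("fully masked image")
  g <- image$geometry
  S <- .pixel_s_matrix(g)
  if (is.null(s_max)) {
    edge_px <- min(g$beam_center[1L] - 1, g$n_pixels[1L] - g$beam_center[1L],
                   g$beam_center[2L] - 1, g$n_pixels[2L] - g$beam_center[2L])
    s_max <- s_of_pixel(g, g$beam_center[1L] + edge_px, g$beam_center[2L])
  }
  use <- image$mask & (S <= s_max)
  sv <- S[use]; cv <- image$counts[use]
  bin <- floor(sv / bin_width) + 1L
  nb <- max(bin)
  npx <- tabulate(bin, nbins = nb)
  sums <- as.vector(rowsum(cv, bin, reorder = TRUE))
  present <- sort(unique(bin))
  mean_counts <- numeric(nb); mean_counts[present] <- sums / npx[present]
  sq <- as.vector(rowsum(cv^2, bin, reorder = TRUE))
  varv <- numeric(nb)
  varv[present] <- pmax(0, sq / npx[present] - mean_counts[present]^2)
  se <- ifelse(npx > 1L, sqrt(varv / pmax(npx, 1L)), NA_real_)
  # abscissa: mean pixel s per bin (not the geometric bin center), which
  # removes the binning bias of the sparse innermost annuli
  s_mean <- numeric(nb)
  s_mean[present] <- as.vector(rowsum(sv, bin, reorder = TRUE)) / npx[present]
  centers <- (seq_len(nb) - 0.5) * bin_width
  keep <- npx > 0L
  out <- diffraction_curve(s_mean[keep], mean_counts[keep], role = "total",
                           meta = c(image$meta, list(bin_width = bin_width)))
  attr(out, "n_pixels") <- npx[keep]
  attr(out, "std_error") <- se[keep]
  attr(out, "empty_bins") <- centers[!keep]
  out
}

#' Refine the beam center of a radially structured image
#'
#' Local grid search around \code{initial} for the center minimizing the
#' mean within-annulus variance (sharpest rings). Two stages: integer grid
#' within \code{half_width} pixels, then quarter-pixel refinement.
#' Deterministic. A flat image yields no usable gradient: the initial center
#' is returned with a warning and attribute \code{refined = FALSE}.
#'
#' @param image A \code{detector_image}.
#' @param initial (row, col) starting center; defaults to the geometry's.
#' @param half_width Search half-width in pixels (default 4).
#' @param bin_width Annulus width in inverse Angstrom for the sharpness
#'   metric.
#' @return Numeric (row, col) refined center with attribute \code{refined}.
#' @export
find_center <- function(image, initial = NULL, half_width = 4,
                        bin_width = 0.02) {
  stopifnot(inherits(image, "detector_image"))
  g <- image$geometry
  if (is.null(initial)) initial <- g$beam_center
  cv_all <- image$counts[image$mask]
  if (stats::sd(cv_all) < 1e-12 || all(cv_all == cv_all[1L])) {
    warning("image has no radial structure; returning initial center")
    return(structure(as.numeric(initial), refined = FALSE))
  }
  score <- function(center) {
    S <- .pixel_s_matrix(g, beam_center = center)
    use <- image$mask
    sv <- S[use]; cv <- image$counts[use]
    bin <- floor(sv / bin_width) + 1L
    nb <- max(bin)
    npx <- tabulate(bin, nbins = nb)
    sums <- numeric(nb); sums[sort(unique(bin))] <-
      as.vector(rowsum(cv, bin, reorder = TRUE))
    sq <- numeric(nb); sq[sort(unique(bin))] <-
      as.vector(rowsum(cv^2, bin, reorder = TRUE))
    ok <- npx > 1L
    mu <- sums[ok] / npx[ok]
    sum(sq[ok] - npx[ok] * mu^2) / sum(npx[ok])  # pooled within-bin variance
  }
  best <- as.numeric(initial); best_sc <- score(best)
  for (step in c(1, 0.25)) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      offs <- expand.grid(dr = c(-step, 0, step), dc = c(-step, 0, step))
      for (k in seq_len(nrow(offs))) {
        cand <- best + c(offs$dr[k], offs$dc[k])
        if (abs(cand[1L] - initial[1L]) > half_width ||
            abs(cand[2L] - initial[2L]) > half_width) next
        if (all(cand == best)) next
        sc <- score(cand)
        if (sc < best_sc - 1e-12) {
          best <- cand; best_sc <- sc; improved <- TRUE
        }
      }
    }
  }
  structure(best, refined = TRUE)
}
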