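# Molecular geometries: construction, XYZ I/O, pair distances, the embedded
# glycerol reference conformer.

.atomic_masses <- c(H = 1.008, C = 12.011, O = 15.999)

#' Construct a molecular geometry
#'
#' @param elements Character vector of element symbols (must be registered in
#'   the scattering-factor table; H, C, O by default).
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param name Free-text name carried through I/O.
#' @param check If \code{TRUE} (default) validate invariants: at least one
#'   atom, finite coordinates, known elements, and no two atoms closer than
#'   0.5 Angstrom.
#' @return Object of class \code{mol_geometry} with fields \code{elements},
#'   \code{coords}, \code{name}.
#' @export
molecular_geometry <- function(elements, coords, name = "", check = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (length(elements) != nrow(coords))
    stop("elements and coords disagree on atom count")
  g <- structure(list(elements = as.character(elements), coords = coords,
                      name = as.character(name)[1L]),
                 class = "mol_geometry")
  if (check) validate_geometry(g)
  g
}

#' Validate a molecular geometry's invariants
#' @param geom A \code{mol_geometry}.
#' @param table Scattering table used as the element registry.
#' @return The geometry, invisibly; errors if an invariant is violated.
#' @export
validate_geometry <- function(geom, table = scattering_table()) {
  stopifnot(inherits(geom, "mol_geometry"))
  n <- nrow(geom$coords)
  if (n < 1L) stop("geometry must contain at least one atom")
  if (!all(is.finite(geom$coords))) stop("non-finite coordinate")
  unknown <- unique(geom$elements[!has_element(table, geom$elements)])
  if (length(unknown))
    stop("element(s) not in scattering-factor registry: ",
         paste(unknown, collapse = ", "))
  if (n > 1L) {
    dmin <- min(stats::dist(geom$coords))
    if (dmin < 0.5)
      stop(sprintf("atoms closer than 0.5 Angstrom (min %.3f)", dmin))
  }
  invisible(geom)
}

#' @export
print.mol_geometry <- function(x, ...) {
  tab <- table(x$elements)
  cat(sprintf("<mol_geometry> %s: %d atoms (%s)\n",
              if (nzchar(x$name)) x$name else "unnamed",
              nrow(x$coords),
              paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", ")))
  invisible(x)
}

#' Number of atoms
#' @param geom A \code{mol_geometry}.
#' @return Integer atom count.
#' @export
n_atoms <- function(geom) nrow(geom$coords)

#' Molar mass of a geometry
#' @param geom A \code{mol_geometry}.
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(geom) {
  m <- .atomic_masses[geom$elements]
  if (anyNA(m)) stop("no tabulated mass for element(s): ",
                     paste(unique(geom$elements[is.na(m)]), collapse = ", "))
  sum(m)
}

#' Read a molecular geometry from an XYZ file
#'
#' Standard XYZ layout: first line atom count, second line free comment,
#' then one \code{element x y z} record per atom, coordinates in Angstrom.
#'
#' @param path File path.
#' @return A \code{mol_geometry}; the comment line becomes its \code{name}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error at line 1: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error at line 1: malformed atom count '", lines[1L], "'")
  if (length(lines) < 2L + n)
    stop(sprintf("XYZ parse error at line %d: count line says %d atoms but only %d records present",
                 length(lines) + 1L, n, length(lines) - 2L))
  comment <- lines[2L]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- 2L + i
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(parts) < 4L)
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ln))
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(xyz))
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln))
    elements[i] <- parts[1L]
    coords[i, ] <- xyz
  }
  tab <- scattering_table()
  unknown <- unique(elements[!has_element(tab, elements)])
  if (length(unknown))
    stop("XYZ parse error: unknown element symbol(s): ",
         paste(unknown, collapse = ", "))
  molecular_geometry(elements, coords, name = comment)
}

#' Write a molecular geometry to an XYZ file
#'
#' @param geom A \code{mol_geometry}.
#' @param path Output path.
#' @param digits Decimal places for coordinates (default 6, so a read/write
#'   round trip reproduces coordinates to 1e-6 Angstrom).
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(geom, path, digits = 6L) {
  validate_geometry(geom)
  fmt <- sprintf("%%-2s %%.%df %%.%df %%.%df", digits, digits, digits)
  rec <- sprintf(fmt, geom$elements,
                 geom$coords[, 1L], geom$coords[, 2L], geom$coords[, 3L])
  writeLines(c(as.character(nrow(geom$coords)), geom$name, rec), con = path)
  invisible(path)
}

# Reference conformer of glycerol (propane-1,2,3-triol, C3H8O3), one fixed
# gauche conformer from force-field-optimized standard internal coordinates,
# centered on the centroid. Bonded C-O 1.42-1.43 A, C-C 1.53 A; non-bonded
# intramolecular C...O pairs cluster at 2.40-2.43 A.
.glycerol_elements <- c("C", "C", "C", "O", "O", "O",
                        "H", "H", "H", "H", "H", "H", "H", "H")
.glycerol_coords <- matrix(c(
   1.230234,  0.671187, -0.386866,
   0.133385,  0.174978,  0.552053,
  -0.935106, -0.637542, -0.183769,
   1.878799, -0.414620, -1.037557,
  -0.494280,  1.296079,  1.187529,
  -1.969927, -0.971174,  0.749656,
   2.616485, -0.034382, -1.546396,
   1.975484,  1.241981,  0.178213,
   0.815575,  1.342597, -1.147080,
   0.568080, -0.445419,  1.344506,
  -1.296833,  0.918423,  1.602818,
  -0.523491, -1.561979, -0.599501,
  -1.395116, -0.046979, -0.982600,
  -2.603289, -1.533150,  0.268996), ncol = 3L, byrow = TRUE)

#' Embedded glycerol reference conformer
#'
#' Returns the fixed C3H8O3 conformer shipped with the package (14 atoms:
#' 3 C, 3 O, 8 H). Identical coordinates on every call.
#'
#' @return A \code{mol_geometry} named \code{"glycerol"}.
#' @export
build_glycerol <- function() {
  molecular_geometry(.glycerol_elements, .glycerol_coords, name = "glycerol")
}

#' All interatomic pair distances
#'
#' @param geom A \code{mol_geometry}.
#' @return A data frame with one row per unordered atom pair: columns
#'   \code{element_i}, \code{element_j}, \code{r} (Angstrom). Exactly
#'   \eqn{N(N-1)/2} rows; zero rows for a single atom.
#' @export
pair_distances <- function(geom) {
  stopifnot(inherits(geom, "mol_geometry"))
  n <- nrow(geom$coords)
  if (n < 2L)
    return(data.frame(element_i = character(), element_j = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  d <- as.vector(stats::dist(geom$coords))
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  # dist() enumerates column-major lower triangle: (2,1),(3,1),...,(n,1),(3,2),...
  ord <- order(ij[, 2L], ij[, 1L])
  ij <- ij[ord, , drop = FALSE]
  data.frame(element_i = geom$elements[ij[, 2L]],
             element_j = geom$elements[ij[, 1L]],
             r = d, stringsAsFactors = FALSE)
}

# rigid-body helpers used by the droplet packer and tests
.rotate_geometry <- function(geom, rotation) {
  geom$coords <- geom$coords %*% t(rotation)
  geom
}

.translate_geometry <- function(geom, shift) {
  geom$coords <- sweep(geom$coords, 2L, shift, "+")
  geom
}

# uniform random rotation matrix from a random unit quaternion
.random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
         3L, 3L, byrow = TRUE)
}
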