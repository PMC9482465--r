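# Plain-text curve I/O and TIFF/text detector-image I/O.

#' Write a diffraction curve as two-column text
#'
#' Columns: s (inverse Angstrom), intensity. Header lines prefixed \code{#}
#' carry the role and any scalar metadata.
#'
#' @param curve A \code{diffraction_curve}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "diffraction_curve"))
  hdr <- c(sprintf("# role: %s", curve$role))
  for (nm in names(curve$meta)) {
    v <- curve$meta[[nm]]
    if (is.atomic(v) && length(v) >= 1L)
      hdr <- c(hdr, sprintf("# %s: %s", nm, paste(v, collapse = ",")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(s = curve$s, intensity = curve$values),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column curve file
#'
#' @param path File written by \code{write_curve} (or any two-column text
#'   file with optional \code{#} headers).
#' @param role Role to assign if the header does not carry one.
#' @return A \code{diffraction_curve}.
#' @export
read_curve <- function(path, role = "total") {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexec("^# role: (.+)$", hdr))
  found <- Filter(length, m)
  if (length(found)) role <- found[[1L]][2L]
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  diffraction_curve(dat[[1L]], dat[[2L]], role = role)
}

#' Write a detector image (16-bit TIFF or plain-text matrix)
#'
#' TIFF output scales counts into the 16-bit range and records the scale in
#' a plain-text sidecar (\code{<path>.meta}) together with the detector
#' geometry and seed, so \code{read_image} reconstructs counts exactly for
#' integer counts up to the recorded maximum. Paths not ending in
#' \code{.tif/.tiff} are written as whitespace-delimited text matrices with
#' \code{#} header lines.
#'
#' @param image A \code{detector_image}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "detector_image"))
  g <- image$geometry
  meta <- c(
    sprintf("n_rows: %d", g$n_pixels[1L]),
    sprintf("n_cols: %d", g$n_pixels[2L]),
    sprintf("pixel_pitch_mm: %.10g", g$pixel_pitch),
    sprintf("camera_length_mm: %.10g", g$camera_length),
    sprintf("accel_voltage_kv: %.10g", g$accel_voltage),
    sprintf("beam_center: %.6f %.6f", g$beam_center[1L], g$beam_center[2L]),
    sprintf("seed: %s", if (is.null(image$meta$seed)) "none" else image$meta$seed),
    sprintf("masked_pixels: %d", sum(!image$mask)))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    cmax <- max(image$counts, 1)
    scale <- 65535 / cmax
    tiff::writeTIFF(round(image$counts * scale) / 65535, path,
                    bits.per.sample = 16L)
    writeLines(c(meta, sprintf("count_scale: %.10g", scale)),
               paste0(path, ".meta"))
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", meta), con)
    utils::write.table(image$counts, con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

.parse_meta_block <- function(lines) {
  kv <- strsplit(sub("^#\\s*", "", lines), ":\\s*")
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = ":"), character(1L))
  names(vals) <- vapply(kv, `[[`, character(1L), 1L)
  vals
}

#' Read a detector image written by \code{write_image}
#'
#' @param path TIFF path (with sidecar \code{<path>.meta}) or text-matrix
#'   path.
#' @return A \code{detector_image}.
#' @export
read_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    meta_path <- paste0(path, ".meta")
    if (!file.exists(meta_path)) stop("missing sidecar metadata: ", meta_path)
    vals <- .parse_meta_block(readLines(meta_path, warn = FALSE))
    img01 <- tiff::readTIFF(path, as.is = FALSE)
    counts <- round(img01 * 65535 / as.numeric(vals[["count_scale"]]))
  } else {
    lines <- readLines(path, warn = FALSE)
    vals <- .parse_meta_block(grep("^#", lines, value = TRUE))
    counts <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)]))
    dimnames(counts) <- NULL
  }
  g <- detector_geometry(
    n_pixels = c(as.integer(vals[["n_rows"]]), as.integer(vals[["n_cols"]])),
    pixel_pitch = as.numeric(vals[["pixel_pitch_mm"]]),
    camera_length = as.numeric(vals[["camera_length_mm"]]),
    accel_voltage = as.numeric(vals[["accel_voltage_kv"]]),
    beam_center = as.numeric(strsplit(vals[["beam_center"]], "\\s+")[[1L]]))
  seed <- vals[["seed"]]
  detector_image(counts, g,
                 meta = list(seed = if (identical(seed, "none")) NULL
                             else as.integer(seed)))
}
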