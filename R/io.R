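#' Write / read a sinogram as CSV with a JSON sidecar header
#'
#' The values go to \code{<path>} as a plain CSV matrix (rows = angles,
#' columns = detectors); the geometry and noise metadata go to
#' \code{<path>.json}.
#'
#' @param y a \linkS4class{Sinogram}.
#' @param path CSV file path.
#' @return \code{writeSinogram}: the path, invisibly.
#'   \code{readSinogram}: a \linkS4class{Sinogram}.
#' @export
writeSinogram <- function(y, path) {
  stopifnot(is(y, "Sinogram"))
  utils::write.table(y@values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  g <- y@geometry
  meta <- list(beam_type = g@beamType,
               angles = g@angles,
               n_detectors = g@nDetectors,
               detector_spacing = g@detectorSpacing,
               angular_range = g@angularRange,
               noise_level = y@noiseLevel,
               noise_seed = if (is.na(y@noiseSeed)) NULL else y@noiseSeed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- new("ScanGeometry",
              beamType = meta$beam_type,
              angles = as.numeric(meta$angles),
              nDetectors = as.integer(meta$n_detectors),
              detectorSpacing = as.numeric(meta$detector_spacing),
              angularRange = as.numeric(meta$angular_range))
  new("Sinogram", values = v, geometry = geom,
      noiseLevel = as.numeric(meta$noise_level %||% 0),
      noiseSeed = as.integer(meta$noise_seed %||% NA_integer_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a pixel image as CSV (and optionally PNG)
#'
#' @param img numeric matrix.
#' @param path file path; \code{writeImagePNG} rescales to [0, 1] over
#'   \code{range} for the 8-bit grayscale output.
#' @param range dynamic range used by the PNG writer (default the image
#'   range).
#' @return the path, invisibly (writers); a numeric matrix (reader).
#' @export
writeImageCSV <- function(img, path) {
  utils::write.table(img, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeImageCSV
#' @export
readImageCSV <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(v) <- NULL
  v
}

#' @rdname writeImageCSV
#' @export
writeImagePNG <- function(img, path, range = NULL) {
  if (is.null(range)) range <- range(img)
  span <- diff(range)
  z <- if (span > 0) (img - range[1]) / span else img * 0
  # image rows are the y axis (bottom-up); PNG rows are top-down
  png::writePNG(z[nrow(z):1, , drop = FALSE], path)
  invisible(path)
}

#' Reader stub for MATLAB sinogram files
#'
#' Real-scanner datasets distributed as \code{.mat} files are outside the
#' simulation scope of this package; this stub documents the expected
#' layout and fails with guidance.
#'
#' @param path path to a \code{.mat} file.
#' @export
readMatSinogram <- function(path) {
  stop("MAT-file sinogram input is not supported; export the sinogram ",
       "matrix to CSV and the geometry to a JSON header (see ",
       "?readSinogram) instead.")
}
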