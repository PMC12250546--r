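#' @import methods
#' @importFrom Matrix sparseMatrix t crossprod colSums rowSums nnzero
NULL

#' Parallel-beam scan geometry
#'
#' Describes a parallel-beam acquisition: the ordered set of projection
#' angles, the number of detector bins and their spacing (in pixel units).
#' Angles are sampled equally spaced on the half-open interval
#' \eqn{[\theta_{min}, \theta_{max})} so that redundant views (e.g. 0 and
#' \eqn{\pi}) are never duplicated.
#'
#' @slot beamType character, currently only \code{"parallel"}.
#' @slot angles numeric vector of projection angles in radians, strictly
#'   increasing, all in \eqn{[0, 2\pi)}.
#' @slot nDetectors integer, number of detector bins per view.
#' @slot detectorSpacing numeric, detector pitch in pixel units.
#' @slot angularRange numeric length-2, the half-open range the angles were
#'   drawn from.
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(
    beamType = "character",
    angles = "numeric",
    nDetectors = "integer",
    detectorSpacing = "numeric",
    angularRange = "numeric"
  )
)

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (!identical(object@beamType, "parallel"))
    msg <- c(msg, "beamType must be 'parallel' (fan beam is reserved)")
  a <- object@angles
  if (length(a) < 1L || any(!is.finite(a)))
    msg <- c(msg, "angles must be a non-empty finite vector")
  if (any(a < 0) || any(a >= 2 * pi))
    msg <- c(msg, "all angles must lie in [0, 2*pi)")
  if (length(a) > 1L && any(diff(a) <= 0))
    msg <- c(msg, "angles must be strictly increasing")
  if (object@nDetectors < 1L)
    msg <- c(msg, "nDetectors must be positive")
  if (object@detectorSpacing <= 0)
    msg <- c(msg, "detectorSpacing must be positive")
  if (length(msg)) msg else TRUE
})

#' Sparse tomographic system matrix
#'
#' The discrete projection operator \eqn{A} with one row per (angle,
#' detector) ray and one column per image pixel; entries are exact
#' ray--pixel intersection lengths (Siddon traversal), so the adjoint
#' \eqn{A^T} is the exact backprojector.
#'
#' @slot weights a \code{dgCMatrix}, rows = rays (angle-major), columns =
#'   pixels in R column-major image order.
#' @slot geometry the \linkS4class{ScanGeometry} the matrix was built for.
#' @slot gridSize integer, side length of the square pixel grid.
#' @exportClass SystemMatrix
setClass("SystemMatrix",
  representation(
    weights = "dgCMatrix",
    geometry = "ScanGeometry",
    gridSize = "integer"
  )
)

setValidity("SystemMatrix", function(object) {
  msg <- character()
  g <- object@geometry
  if (nrow(object@weights) != length(g@angles) * g@nDetectors)
    msg <- c(msg, "row count must equal n_angles * n_detectors")
  if (ncol(object@weights) != object@gridSize^2)
    msg <- c(msg, "column count must equal gridSize^2")
  if (length(object@weights@x) && any(object@weights@x <= 0))
    msg <- c(msg, "all stored weights must be > 0")
  if (length(msg)) msg else TRUE
})

#' Sinogram container
#'
#' Projection data indexed (angle, detector) together with the geometry
#' that produced it and, when simulated noise was added, the noise level
#' and seed.
#'
#' @slot values numeric matrix, \code{n_angles x n_detectors}.
#' @slot geometry the \linkS4class{ScanGeometry}.
#' @slot noiseLevel numeric, relative Gaussian noise level n (sd = n * max
#'   of the clean sinogram); 0 for noiseless data.
#' @slot noiseSeed integer, RNG seed of the noise realization (NA if none).
#' @exportClass Sinogram
setClass("Sinogram",
  representation(
    values = "matrix",
    geometry = "ScanGeometry",
    noiseLevel = "numeric",
    noiseSeed = "integer"
  ),
  prototype(noiseLevel = 0, noiseSeed = NA_integer_)
)

setValidity("Sinogram", function(object) {
  msg <- character()
  g <- object@geometry
  if (!identical(dim(object@values),
                 c(length(g@angles), as.integer(g@nDetectors))))
    msg <- c(msg, "values must be n_angles x n_detectors")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "sinogram values must be finite")
  if (object@noiseLevel < 0)
    msg <- c(msg, "noiseLevel must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Gaussian radial-basis dictionary
#'
#' One Gaussian atom per (pixel, scale) pair, sampled on the pixel grid in
#' normalized [0,1] x [0,1] domain coordinates. The basis matrix maps a
#' coefficient vector \eqn{\alpha} to the level-set field
#' \eqn{\phi = M\alpha}. Entries at or below \code{truncation} are dropped,
#' which keeps the matrix sparse for narrow atoms.
#'
#' @slot basis numeric matrix or \code{dgCMatrix}, \code{n_pixels x
#'   n_atoms}; atoms ordered pixel-major, then scale.
#' @slot centers two-column matrix of atom centers (normalized domain).
#' @slot gammas numeric vector, atom width per scale (normalized domain
#'   units).
#' @slot scaleIndex integer vector, scale of each atom (1-based).
#' @slot gridSize integer grid side.
#' @slot truncation numeric in [0,1), the dropped-entry threshold.
#' @exportClass GaussianDictionary
setClass("GaussianDictionary",
  representation(
    basis = "ANY",
    centers = "matrix",
    gammas = "numeric",
    scaleIndex = "integer",
    gridSize = "integer",
    truncation = "numeric"
  )
)

setValidity("GaussianDictionary", function(object) {
  msg <- character()
  nAtoms <- ncol(object@basis)
  if (nrow(object@basis) != object@gridSize^2)
    msg <- c(msg, "basis must have gridSize^2 rows")
  if (nAtoms != object@gridSize^2 * length(object@gammas))
    msg <- c(msg, "one atom per (pixel, scale) pair required")
  if (nrow(object@centers) != nAtoms || length(object@scaleIndex) != nAtoms)
    msg <- c(msg, "centers/scaleIndex length must match atom count")
  if (any(object@gammas <= 0))
    msg <- c(msg, "all gammas must be > 0")
  if (object@truncation < 0 || object@truncation >= 1)
    msg <- c(msg, "truncation must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Reconstruction result
#'
#' Output of \code{\link{plsReconstruct}} /
#' \code{\link{plsReconstructMultiphase}}: the fitted coefficients, the
#' level-set field(s), the continuous image model, the hard-quantized
#' discrete image, and the objective trace of the OWL-QN run.
#'
#' @slot alpha numeric matrix, one column of coefficients per level set.
#' @slot phi list of level-set fields (gridSize x gridSize matrices).
#' @slot u numeric matrix, the continuous (smoothed-Heaviside) image model.
#' @slot quantized numeric matrix taking values only in \code{grayLevels}.
#' @slot grayLevels numeric, the known discrete gray levels.
#' @slot lambda numeric, the l1 weight used.
#' @slot objectiveTrace numeric, accepted objective values per iteration.
#' @slot info list of solver diagnostics and the configuration used.
#' @exportClass ReconstructionResult
setClass("ReconstructionResult",
  representation(
    alpha = "matrix",
    phi = "list",
    u = "matrix",
    quantized = "matrix",
    grayLevels = "numeric",
    lambda = "numeric",
    objectiveTrace = "numeric",
    info = "list"
  )
)

setValidity("ReconstructionResult", function(object) {
  msg <- character()
  if (!all(object@quantized %in% object@grayLevels))
    msg <- c(msg, "quantized image must take values in grayLevels only")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf(
    "ScanGeometry (%s beam): %d angles in [%.4g, %.4g), %d detectors, spacing %.3g px\n",
    object@beamType, length(object@angles), object@angularRange[1],
    object@angularRange[2], object@nDetectors, object@detectorSpacing))
})

setMethod("show", "SystemMatrix", function(object) {
  w <- object@weights
  cat(sprintf(
    "SystemMatrix: %d rays x %d pixels (grid %d^2), %d nonzeros (%.2f%% dense)\n",
    nrow(w), ncol(w), object@gridSize, Matrix::nnzero(w),
    100 * Matrix::nnzero(w) / prod(dim(w))))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d detectors, range [%.4g, %.4g]",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
  if (object@noiseLevel > 0)
    cat(sprintf(", Gaussian noise n = %g (seed %d)",
                object@noiseLevel, object@noiseSeed))
  cat("\n")
})

setMethod("show", "GaussianDictionary", function(object) {
  cat(sprintf(
    "GaussianDictionary: %d atoms (%d scales) on %d^2 grid, gamma = %s, truncation %g\n",
    ncol(object@basis), length(object@gammas), object@gridSize,
    paste(signif(object@gammas, 3), collapse = ", "), object@truncation))
})

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf(
    "ReconstructionResult: %d level set(s), grid %d^2, lambda = %g\n",
    ncol(object@alpha), nrow(object@u), object@lambda))
  cat(sprintf("  gray levels: %s; final objective %.6g (%d iterations)\n",
              paste(object@grayLevels, collapse = ", "),
              utils::tail(object@objectiveTrace, 1),
              length(object@objectiveTrace)))
})

#' @rdname ScanGeometry-class
#' @param object,x a \code{ScanGeometry}
#' @export
angles <- function(x) x@angles

#' @rdname ScanGeometry-class
#' @export
nDetectors <- function(x) x@nDetectors

#' @rdname ScanGeometry-class
#' @export
detectorSpacing <- function(x) x@detectorSpacing

#' @rdname Sinogram-class
#' @param x a \code{Sinogram}
#' @export
sinogramValues <- function(x) x@values

#' @rdname Sinogram-class
#' @export
geometry <- function(x) x@geometry

#' @rdname SystemMatrix-class
#' @param x a \code{SystemMatrix}
#' @export
systemWeights <- function(x) x@weights

#' @rdname GaussianDictionary-class
#' @param x a \code{GaussianDictionary}
#' @export
basisMatrix <- function(x) x@basis

#' @rdname ReconstructionResult-class
#' @param x a \code{ReconstructionResult}
#' @export
quantizedImage <- function(x) x@quantized

#' @rdname ReconstructionResult-class
#' @export
continuousImage <- function(x) x@u

#' @rdname ReconstructionResult-class
#' @export
plsCoefficients <- function(x) x@alpha

#' @rdname ReconstructionResult-class
#' @export
objectiveTrace <- function(x) x@objectiveTrace
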