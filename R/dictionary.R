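#' Evaluate a Gaussian radial basis function
#'
#' \eqn{m(x) = \exp(-\|x - x_i\|^2 / (2\gamma^2))}, equivalently
#' \eqn{\exp(-\beta \|x - x_i\|^2)} with \eqn{\beta = 1/(2\gamma^2)}.
#' Coordinates are in the normalized [0,1] x [0,1] image domain.
#'
#' @param x numeric length-2 point, or an n x 2 matrix of points.
#' @param center numeric length-2 atom center.
#' @param gamma positive width (normalized domain units).
#' @return value(s) in (0, 1].
#' @examples
#' gaussianValue(c(0.5, 0.5), c(0.5, 0.5), 0.3) # 1
#' @export
gaussianValue <- function(x, center, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  if (is.matrix(x)) {
    d2 <- (x[, 1] - center[1])^2 + (x[, 2] - center[2])^2
  } else {
    d2 <- sum((x - center)^2)
  }
  exp(-d2 / (2 * gamma^2))
}

#' Build a single- or multiscale Gaussian dictionary
#'
#' Places one Gaussian atom at each pixel center for every width in
#' \code{gammas} ("each pixel has its own basis function") and samples all
#' atoms on the pixel grid, in normalized [0,1] x [0,1] coordinates. Atoms
#' are ordered pixel-major within each scale, scales concatenated, so the
#' multiscale dictionary contains each single-scale dictionary as a
#' contiguous column block. Matrix entries at or below
#' \code{truncation} are dropped; the matrix is stored sparse
#' (\code{dgCMatrix}) when fewer than half the entries survive, dense
#' otherwise.
#'
#' @param gridSize side of the square pixel grid.
#' @param gammas numeric vector of positive atom widths. The conventional
#'   single-scale choice is one value in [0.1, 0.5]; a multiscale
#'   dictionary uses \code{multiscaleGammas()}.
#' @param truncation threshold in [0, 1) below which sampled atom values
#'   are dropped (default 1e-4).
#' @return a \linkS4class{GaussianDictionary}.
#' @examples
#' d <- buildDictionary(8, gammas = 0.3)
#' dim(basisMatrix(d)) # 64 x 64
#' @export
buildDictionary <- function(gridSize, gammas = 0.1, truncation = 1e-4) {
  if (length(gammas) < 1L) stop("gammas must be non-empty")
  if (any(gammas <= 0)) stop("all gammas must be positive")
  if (truncation < 0 || truncation >= 1)
    stop("truncation must be in [0, 1)")
  g <- as.integer(gridSize)
  if (g < 1L) stop("gridSize must be positive")
  cc <- (seq_len(g) - 0.5) / g           # normalized pixel-center coords
  py <- rep(cc, times = g)               # column-major: y fast
  px <- rep(cc, each = g)
  n <- g * g
  blocks <- vector("list", length(gammas))
  d2 <- outer(px, px, "-")^2 + outer(py, py, "-")^2
  for (s in seq_along(gammas)) {
    B <- exp(-d2 / (2 * gammas[s]^2))
    B[B <= truncation] <- 0
    blocks[[s]] <- B
  }
  basis <- if (length(blocks) == 1L) blocks[[1]] else do.call(cbind, blocks)
  dens <- mean(basis > 0)
  if (dens < 0.5) basis <- methods::as(Matrix::Matrix(basis, sparse = TRUE),
                                       "CsparseMatrix")
  new("GaussianDictionary",
      basis = basis,
      centers = cbind(rep(px, length(gammas)), rep(py, length(gammas))),
      gammas = as.numeric(gammas),
      scaleIndex = rep(seq_along(gammas), each = n),
      gridSize = g,
      truncation = as.numeric(truncation))
}

#' Default multiscale width ladder
#'
#' Ten widths equally spaced on [0.1, 0.5] (normalized domain units), the
#' conventional multiscale configuration of ten atoms per pixel.
#'
#' @param n number of scales (default 10).
#' @param range width range (default \code{c(0.1, 0.5)}).
#' @return numeric vector of widths.
#' @export
multiscaleGammas <- function(n = 10, range = c(0.1, 0.5)) {
  seq(range[1], range[2], length.out = n)
}

#' Evaluate the parametric level-set field
#'
#' \eqn{\phi = M \alpha}: the weighted sum of dictionary atoms sampled on
#' the pixel grid.
#'
#' @param dict a \linkS4class{GaussianDictionary}.
#' @param alpha coefficient vector of length \code{ncol(basisMatrix(dict))}.
#' @return \code{gridSize x gridSize} numeric matrix.
#' @export
evaluatePLS <- function(dict, alpha) {
  stopifnot(is(dict, "GaussianDictionary"))
  if (length(alpha) != ncol(dict@basis))
    stop("alpha length does not match the number of atoms")
  phi <- as.numeric(dict@basis %*% alpha)
  matrix(phi, dict@gridSize, dict@gridSize)
}
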