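#' Smooth data-fidelity objective of the PLS reconstruction
#'
#' \eqn{f(\alpha) = \frac{1}{2}\|y - A\,u(x,\alpha)\|_2^2} where the image
#' model \eqn{u} is assembled from the level-set field(s) \eqn{\phi_j = M
#' \alpha_j} through the smoothed Heaviside. For two level sets the
#' coefficient vector is the concatenation \eqn{(\alpha_1, \alpha_2)} over
#' one shared dictionary.
#'
#' @param alpha stacked coefficient vector (\code{nAtoms} per level set).
#' @param A a \linkS4class{SystemMatrix}.
#' @param y a \linkS4class{Sinogram} or ray-major numeric vector.
#' @param dict a \linkS4class{GaussianDictionary}.
#' @param cfg a \code{\link{levelSetConfig}} (2 or 3 gray levels).
#' @return scalar objective value (without the l1 term).
#' @export
smoothObjective <- function(alpha, A, y, dict, cfg) {
  ctx <- plsContext(A, y, dict, cfg)
  ctx$fn(alpha)
}

#' Gradient of \code{\link{smoothObjective}}
#'
#' Chain rule through the level-set model: with residual \eqn{r = A u -
#' y}, one level set gives \eqn{\nabla f = M^T[(u_1 - u_0)\,\delta(\phi -
#' c) \odot A^T r]}; two level sets give the analogous blockwise
#' contraction with the three-region sensitivity fields.
#'
#' @inheritParams smoothObjective
#' @return stacked gradient vector, same length as \code{alpha}.
#' @export
smoothGradient <- function(alpha, A, y, dict, cfg) {
  ctx <- plsContext(A, y, dict, cfg)
  ctx$gr(alpha)
}

# Precomputed closures shared by objective/gradient/driver. y may be a
# Sinogram or a ray-major vector.
plsContext <- function(A, y, dict, cfg) {
  stopifnot(is(A, "SystemMatrix"), is(dict, "GaussianDictionary"))
  if (!inherits(cfg, "LevelSetConfig")) stop("cfg must be a levelSetConfig")
  W <- A@weights
  yv <- if (is(y, "Sinogram")) sinogramVector(y) else as.numeric(y)
  if (any(!is.finite(yv))) stop("sinogram contains non-finite values")
  if (length(yv) != nrow(W)) stop("sinogram length does not match rays")
  M <- dict@basis
  nA <- ncol(M)
  nPhase <- if (length(cfg$grayLevels) == 2L) 1L else 2L
  npix <- nrow(M)
  if (npix != A@gridSize^2)
    stop("dictionary grid does not match system matrix grid")
  split2 <- function(alpha) {
    if (length(alpha) != nPhase * nA)
      stop("alpha length must be ", nPhase, " x ", nA)
    if (nPhase == 1L) list(alpha) else
      list(alpha[seq_len(nA)], alpha[nA + seq_len(nA)])
  }
  makeU <- function(phis) {
    if (nPhase == 1L) composeTwoRegion(phis[[1]], cfg)
    else composeThreeRegion(phis[[1]], phis[[2]], cfg)
  }
  fn <- function(alpha) {
    al <- split2(alpha)
    phis <- lapply(al, function(a) as.numeric(M %*% a))
    r <- as.numeric(W %*% makeU(phis)) - yv
    0.5 * sum(r * r)
  }
  gr <- function(alpha) {
    al <- split2(alpha)
    phis <- lapply(al, function(a) as.numeric(M %*% a))
    r <- as.numeric(W %*% makeU(phis)) - yv
    back <- as.numeric(Matrix::crossprod(W, r))
    if (nPhase == 1L) {
      w <- jacobianTwoRegion(phis[[1]], cfg) * back
      as.numeric(Matrix::crossprod(M, w))
    } else {
      J <- jacobianThreeRegion(phis[[1]], phis[[2]], cfg)
      c(as.numeric(Matrix::crossprod(M, J$d1 * back)),
        as.numeric(Matrix::crossprod(M, J$d2 * back)))
    }
  }
  list(fn = fn, gr = gr, nAtoms = nA, nPhase = nPhase, M = M, W = W,
       yv = yv)
}

# default start: uniform coefficients placing the mean field at the level
# offset c, i.e. the whole domain inside the Heaviside smoothing band
defaultAlpha0 <- function(dict, cfg, nPhase) {
  rs <- as.numeric(dict@basis %*% rep(1, ncol(dict@basis)))
  a <- cfg$c / mean(rs)
  rep(a, nPhase * ncol(dict@basis))
}

#' Hard-quantize level-set fields to the discrete gray levels
#'
#' Two regions: \eqn{u_1} where \eqn{\phi > c}, else \eqn{u_0}. Three
#' regions: \eqn{u_0} where \eqn{\phi_1 \le c}; else \eqn{u_2} where
#' \eqn{\phi_2 > c} and \eqn{u_1} otherwise. The tie \eqn{\phi = c} goes
#' to the lower region (strict inequality defines the object).
#'
#' @param phi level-set field, or list of two fields for three regions.
#' @param cfg a \code{\link{levelSetConfig}}.
#' @return discrete image with values in \code{cfg$grayLevels}.
#' @export
quantizeLevelSet <- function(phi, cfg) {
  u <- cfg$grayLevels
  if (length(u) == 2L) {
    p <- if (is.list(phi)) phi[[1]] else phi
    out <- p
    out[] <- ifelse(p > cfg$c, u[2], u[1])
    out
  } else {
    stopifnot(is.list(phi), length(phi) == 2L)
    p1 <- phi[[1]]; p2 <- phi[[2]]
    out <- p1
    out[] <- u[1]
    out[p1 > cfg$c & p2 <= cfg$c] <- u[2]
    out[p1 > cfg$c & p2 > cfg$c] <- u[3]
    out
  }
}

#' Single-level-set PLS reconstruction
#'
#' Runs Algorithm-style reconstruction for a binary (two gray level)
#' image: the level-set field is expanded in the Gaussian dictionary, the
#' coefficients minimize \eqn{\frac{1}{2}\|y - A u(x,\alpha)\|_2^2 +
#' \lambda \|\alpha\|_1} via OWL-QN, and the result is hard-quantized at
#' \eqn{\phi > c}.
#'
#' @param y a \linkS4class{Sinogram} (or ray-major vector).
#' @param A a \linkS4class{SystemMatrix}.
#' @param dict a \linkS4class{GaussianDictionary} on the same grid.
#' @param cfg a \code{\link{levelSetConfig}} with 2 gray levels.
#' @param lambda l1 regularization weight (> 0).
#' @param options an \code{\link{owlqnOptions}} list.
#' @param alpha0 optional start vector; the default places the mean field
#'   at the level offset \code{c} so the whole domain starts inside the
#'   Heaviside smoothing band.
#' @return a \linkS4class{ReconstructionResult}.
#' @export
plsReconstruct <- function(y, A, dict, cfg = levelSetConfig(),
                           lambda = 1e-3,
                           options = owlqnOptions(maxIterations = 500),
                           alpha0 = NULL) {
  if (length(cfg$grayLevels) != 2L)
    stop("plsReconstruct is the single-level-set driver; use ",
         "plsReconstructMultiphase for 3 gray levels")
  plsDriver(y, A, dict, cfg, lambda, options, alpha0)
}

#' Multiphase (two level set, three gray level) PLS reconstruction
#'
#' Joint OWL-QN optimization of the stacked coefficients
#' \eqn{(\alpha_1, \alpha_2)} of two level-set fields over one shared
#' dictionary, with objective \eqn{\frac{1}{2}\|y - A u\|_2^2 + \lambda
#' (\|\alpha_1\|_1 + \|\alpha_2\|_1)} and the three-region image model.
#'
#' @inheritParams plsReconstruct
#' @param cfg a \code{\link{levelSetConfig}} with 3 gray levels.
#' @return a \linkS4class{ReconstructionResult}.
#' @export
plsReconstructMultiphase <- function(y, A, dict, cfg,
                                     lambda = 1e-3,
                                     options = owlqnOptions(maxIterations = 500),
                                     alpha0 = NULL) {
  if (length(cfg$grayLevels) != 3L)
    stop("multiphase reconstruction requires 3 gray levels")
  plsDriver(y, A, dict, cfg, lambda, options, alpha0)
}

plsDriver <- function(y, A, dict, cfg, lambda, options, alpha0) {
  if (lambda <= 0) stop("lambda must be > 0")
  ctx <- plsContext(A, y, dict, cfg)
  if (is.null(alpha0)) alpha0 <- defaultAlpha0(dict, cfg, ctx$nPhase)
  if (length(alpha0) != ctx$nPhase * ctx$nAtoms)
    stop("alpha0 has the wrong length")
  fit <- owlqnMinimize(ctx$fn, ctx$gr, alpha0, C = lambda,
                       options = options)
  g <- dict@gridSize
  alphaMat <- matrix(fit$x, ncol = ctx$nPhase)
  phis <- lapply(seq_len(ctx$nPhase), function(j)
    evaluatePLS(dict, alphaMat[, j]))
  u <- if (ctx$nPhase == 1L) composeTwoRegion(phis[[1]], cfg)
       else composeThreeRegion(phis[[1]], phis[[2]], cfg)
  q <- quantizeLevelSet(if (ctx$nPhase == 1L) phis[[1]] else phis, cfg)
  new("ReconstructionResult",
      alpha = alphaMat, phi = phis,
      u = matrix(u, g, g), quantized = matrix(q, g, g),
      grayLevels = cfg$grayLevels, lambda = lambda,
      objectiveTrace = fit$trace,
      info = list(iterations = fit$iterations,
                  converged = fit$converged,
                  finalObjective = fit$value,
                  nnz = sum(fit$x != 0),
                  epsilon = cfg$epsilon, c = cfg$c,
                  options = options))
}

#' Scan the l1 weight over a grid and keep the best reconstruction
#'
#' Reruns the reconstruction for each \eqn{\lambda} in \code{lambdaGrid}
#' (the usual practice of solving for several small values of
#' \eqn{\lambda} and comparing the resulting quality). With ground truth
#' available the selection criterion is the mean Dice coefficient over
#' foreground levels; without it, the data misfit of the quantized image
#' \eqn{\frac{1}{2}\|y - A u_q\|^2} is minimized. Ties go to the larger
#' (sparser) \eqn{\lambda}. The scan is deterministic.
#'
#' @inheritParams plsReconstruct
#' @param lambdaGrid positive values to try; default
#'   \code{c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2)}.
#' @param truth optional ground-truth discrete image for the selection
#'   criterion.
#' @return list with \code{best} (a \linkS4class{ReconstructionResult}),
#'   \code{lambda} (the selected value), \code{scores} (named per-lambda
#'   criterion values; higher is better), and \code{results} (all fits).
#' @export
lambdaScan <- function(y, A, dict, cfg = levelSetConfig(),
                       lambdaGrid = c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2),
                       truth = NULL,
                       options = owlqnOptions(maxIterations = 500),
                       alpha0 = NULL) {
  if (!length(lambdaGrid)) stop("lambdaGrid must be non-empty")
  lambdaGrid <- sort(lambdaGrid)
  nPhase <- if (length(cfg$grayLevels) == 2L) 1L else 2L
  runs <- lapply(lambdaGrid, function(lam)
    plsDriver(y, A, dict, cfg, lam, options, alpha0))
  W <- A@weights
  yv <- if (is(y, "Sinogram")) sinogramVector(y) else as.numeric(y)
  scores <- vapply(runs, function(res) {
    if (!is.null(truth)) {
      fg <- cfg$grayLevels[-1]
      mean(vapply(fg, function(lv)
        diceCoefficient(truth, res@quantized, lv, cfg$grayLevels),
        numeric(1)))
    } else {
      r <- as.numeric(W %*% as.numeric(res@quantized)) - yv
      -0.5 * sum(r * r)
    }
  }, numeric(1))
  names(scores) <- as.character(lambdaGrid)
  # which.max takes the first maximum; reverse so ties pick the larger lambda
  bestIdx <- length(scores) + 1L - which.max(rev(scores))
  list(best = runs[[bestIdx]], lambda = lambdaGrid[bestIdx],
       scores = scores, results = runs)
}
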