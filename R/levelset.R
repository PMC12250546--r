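#' Level-set model configuration
#'
#' Holds the smoothed-Heaviside half-width \code{epsilon}, the level
#' offset \code{c} defining the object as \eqn{\{\phi > c\}}, and the
#' known discrete gray levels (2 for a single level set, 3 for two).
#' The recommended \code{epsilon > c} keeps a zero initial field inside
#' the smoothing band, so first gradients are informative.
#'
#' @param epsilon smoothing half-width in level-set-field units (> 0).
#' @param c level offset, a small positive value.
#' @param grayLevels strictly increasing numeric vector of length 2 or 3.
#' @return an object of class \code{LevelSetConfig} (a validated list).
#' @examples
#' levelSetConfig(grayLevels = c(0, 1))
#' @export
levelSetConfig <- function(epsilon = 0.1, c = 0.05, grayLevels = c(0, 1)) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (c <= 0) stop("c must be a small positive value")
  if (!length(grayLevels) %in% c(2L, 3L))
    stop("grayLevels must have length 2 or 3")
  d <- diff(grayLevels)
  # ascending; a tied upper pair (u1 == u2) is allowed so the three-level
  # model can degenerate to the merged two-region object
  if (any(d < 0) || all(d == 0) || (length(grayLevels) == 3L && d[1] == 0))
    stop("grayLevels must be increasing (only u1 == u2 may tie)")
  if (epsilon <= c)
    warning("epsilon <= c: an all-zero initial field lies outside the ",
            "smoothing band and gives zero first gradients")
  structure(list(epsilon = epsilon, c = c,
                 grayLevels = as.numeric(grayLevels)),
            class = "LevelSetConfig")
}

#' Smoothed Heaviside step
#'
#' Continuous ramp approximation of the unit step over \eqn{[-\epsilon,
#' \epsilon]}: 1 for \eqn{t > \epsilon}, 0 for \eqn{t < -\epsilon}, and
#' \eqn{1/2 + t/(2\epsilon) + \sin(\pi t/\epsilon)/(2\pi)} inside the band.
#'
#' @param t numeric scalar, vector or matrix.
#' @param epsilon positive smoothing half-width.
#' @return values in [0, 1], same shape as \code{t}.
#' @export
smoothHeaviside <- function(t, epsilon) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  h <- 0.5 + t / (2 * epsilon) + sin(pi * t / epsilon) / (2 * pi)
  h[t > epsilon] <- 1
  h[t < -epsilon] <- 0
  h
}

#' Smoothed Dirac delta
#'
#' The exact derivative of \code{\link{smoothHeaviside}}:
#' \eqn{(1 + \cos(\pi t/\epsilon)) / (2\epsilon)} for \eqn{|t| \le
#' \epsilon}, 0 outside, so the analytic gradients of the image model are
#' exactly consistent with the objective.
#'
#' @inheritParams smoothHeaviside
#' @return nonnegative values, same shape as \code{t}.
#' @export
smoothDelta <- function(t, epsilon) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  d <- (1 + cos(pi * t / epsilon)) / (2 * epsilon)
  d[abs(t) > epsilon] <- 0
  d
}

#' Two-region piecewise-constant image model
#'
#' \eqn{u = u_0 (1 - H(\phi - c)) + u_1 H(\phi - c)} elementwise.
#'
#' @param phi level-set field (matrix or vector).
#' @param cfg a \code{\link{levelSetConfig}} with 2 gray levels.
#' @return continuous image model, same shape as \code{phi}.
#' @export
composeTwoRegion <- function(phi, cfg) {
  if (length(cfg$grayLevels) != 2L)
    stop("composeTwoRegion requires exactly 2 gray levels")
  u <- cfg$grayLevels
  H <- smoothHeaviside(phi - cfg$c, cfg$epsilon)
  u[1] * (1 - H) + u[2] * H
}

#' Three-region piecewise-constant image model (two level sets)
#'
#' \eqn{u = u_0 + (u_1 - u_0) H(\phi_1 - c) + (u_2 - u_1) H(\phi_1 - c)
#' H(\phi_2 - c)}, the compact form of the sign-combination expansion
#' \eqn{u_0(1-H_1) + u_1 H_1 (1-H_2) + u_2 H_1 H_2}.
#'
#' @param phi1,phi2 level-set fields of equal shape.
#' @param cfg a \code{\link{levelSetConfig}} with 3 gray levels.
#' @return continuous image model, same shape as the inputs.
#' @export
composeThreeRegion <- function(phi1, phi2, cfg) {
  if (length(cfg$grayLevels) != 3L)
    stop("composeThreeRegion requires exactly 3 gray levels")
  u <- cfg$grayLevels
  H1 <- smoothHeaviside(phi1 - cfg$c, cfg$epsilon)
  H2 <- smoothHeaviside(phi2 - cfg$c, cfg$epsilon)
  u[1] + (u[2] - u[1]) * H1 + (u[3] - u[2]) * H1 * H2
}

#' Pixelwise sensitivity of the two-region model
#'
#' \eqn{\partial u / \partial \phi = (u_1 - u_0)\,\delta(\phi - c)}; the
#' caller contracts this diagonal factor with the dictionary matrix to get
#' \eqn{\partial u / \partial \alpha}.
#'
#' @inheritParams composeTwoRegion
#' @return sensitivity field, same shape as \code{phi}.
#' @export
jacobianTwoRegion <- function(phi, cfg) {
  if (length(cfg$grayLevels) != 2L)
    stop("jacobianTwoRegion requires exactly 2 gray levels")
  u <- cfg$grayLevels
  (u[2] - u[1]) * smoothDelta(phi - cfg$c, cfg$epsilon)
}

#' Pixelwise sensitivities of the three-region model
#'
#' Returns the two diagonal factors
#' \eqn{\partial u/\partial\phi_1 = (u_1-u_0)\delta(\phi_1-c) +
#' (u_2-u_1)\delta(\phi_1-c)H(\phi_2-c)} and
#' \eqn{\partial u/\partial\phi_2 = (u_2-u_1)H(\phi_1-c)\delta(\phi_2-c)}.
#'
#' @inheritParams composeThreeRegion
#' @return list with elements \code{d1} and \code{d2}.
#' @export
jacobianThreeRegion <- function(phi1, phi2, cfg) {
  if (length(cfg$grayLevels) != 3L)
    stop("jacobianThreeRegion requires exactly 3 gray levels")
  u <- cfg$grayLevels
  e <- cfg$epsilon
  d1f <- smoothDelta(phi1 - cfg$c, e)
  H2 <- smoothHeaviside(phi2 - cfg$c, e)
  H1 <- smoothHeaviside(phi1 - cfg$c, e)
  d2f <- smoothDelta(phi2 - cfg$c, e)
  list(d1 = (u[2] - u[1]) * d1f + (u[3] - u[2]) * d1f * H2,
       d2 = (u[3] - u[2]) * H1 * d2f)
}
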