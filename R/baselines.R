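#' Filtered backprojection (parallel beam, Ram-Lak)
#'
#' Classical FBP reference: each projection is convolved with the
#' band-limited ramp (Ram-Lak) kernel via FFT, then smeared back over the
#' image along its rays with linear interpolation between detector bins
#' and weighted by \eqn{\pi / n_{angles}}. No discreteness prior is
#' applied; with dense angular sampling this is the conventional
#' high-quality reference, with few views it shows the usual streaks.
#'
#' @param y a \linkS4class{Sinogram}.
#' @param gridSize side of the reconstruction grid.
#' @return \code{gridSize x gridSize} numeric matrix.
#' @export
fbpReconstruct <- function(y, gridSize) {
  stopifnot(is(y, "Sinogram"))
  geom <- y@geometry
  if (!length(geom@angles)) stop("geometry has no angles")
  g <- as.integer(gridSize)
  nd <- geom@nDetectors
  tau <- geom@detectorSpacing
  # spatial-domain Ram-Lak kernel (band-limited ramp)
  L <- 2^ceiling(log2(2 * nd))
  k <- c(0:(L / 2), (-L / 2 + 1):(-1))
  h <- numeric(L)
  h[k == 0] <- 1 / (4 * tau^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi^2 * k[odd]^2 * tau^2)
  H <- Re(stats::fft(h))
  filt <- matrix(0, nrow(y@values), nd)
  for (a in seq_len(nrow(y@values))) {
    p <- c(y@values[a, ], numeric(L - nd))
    q <- Re(stats::fft(stats::fft(p) * H, inverse = TRUE)) / L
    filt[a, ] <- q[seq_len(nd)] * tau
  }
  offs <- detectorOffsets(geom)
  cc <- seq_len(g) - 0.5 - g / 2
  Y <- matrix(rep(cc, times = g), g, g)
  X <- matrix(rep(cc, each = g), g, g)
  img <- matrix(0, g, g)
  for (a in seq_along(geom@angles)) {
    th <- geom@angles[a]
    t <- X * cos(th) + Y * sin(th)
    # linear interpolation into the detector bank
    pos <- (t - offs[1]) / tau + 1
    i0 <- floor(pos)
    w <- pos - i0
    v0 <- ifelse(i0 >= 1 & i0 <= nd, filt[a, pmin(pmax(i0, 1), nd)], 0)
    v1 <- ifelse(i0 + 1 >= 1 & i0 + 1 <= nd,
                 filt[a, pmin(pmax(i0 + 1, 1), nd)], 0)
    img <- img + (1 - w) * v0 + w * v1
  }
  img * pi / length(geom@angles)
}

#' Total-variation reconstruction via Chambolle-Pock
#'
#' Solves \eqn{\min_{x \ge 0} \frac{1}{2}\|Ax - y\|_2^2 + \lambda\,
#' \mathrm{TV}(x)} with the first-order primal-dual scheme: isotropic TV
#' with forward differences and Neumann boundary, nonnegativity enforced
#' by the primal proximal step, and step sizes \eqn{\tau = \sigma =
#' 0.95/\|K\|} with the operator norm of the stacked operator
#' \eqn{K = [A; \nabla]} estimated by power iteration.
#'
#' @param y a \linkS4class{Sinogram}.
#' @param A a \linkS4class{SystemMatrix}.
#' @param lambda TV weight (default 8e-3).
#' @param tol relative-change stopping tolerance (default 1e-6).
#' @param maxIterations iteration cap (default 500).
#' @return \code{gridSize x gridSize} nonnegative matrix, with the primal
#'   objective trace in attribute \code{"trace"}.
#' @export
tvReconstruct <- function(y, A, lambda = 8e-3, tol = 1e-6,
                          maxIterations = 500) {
  stopifnot(is(A, "SystemMatrix"), lambda > 0, tol > 0)
  W <- A@weights
  yv <- if (is(y, "Sinogram")) sinogramVector(y) else as.numeric(y)
  g <- A@gridSize
  n <- g * g
  gradOp <- function(x) {
    X <- matrix(x, g, g)
    dx <- cbind(X[, -1] - X[, -g], numeric(g))      # d/dx, Neumann
    dy <- rbind(X[-1, ] - X[-g, ], numeric(g))      # d/dy, Neumann
    list(dx = dx, dy = dy)
  }
  divOp <- function(px, py) {
    # negative adjoint of gradOp
    dvx <- px
    dvx[, -1] <- px[, -1] - px[, -g]
    dvx[, g] <- -px[, g - 1]
    dvx[, 1] <- px[, 1]
    dvy <- py
    dvy[-1, ] <- py[-1, ] - py[-g, ]
    dvy[g, ] <- -py[g - 1, ]
    dvy[1, ] <- py[1, ]
    as.numeric(dvx + dvy)
  }
  # operator norm of K = [A; grad] by power iteration
  z <- stats::runif(n)
  z <- z / sqrt(sum(z^2))
  for (i in 1:30) {
    gz <- gradOp(z)
    w <- as.numeric(Matrix::crossprod(W, W %*% z)) - divOp(gz$dx, gz$dy)
    nz <- sqrt(sum(w^2))
    z <- w / nz
  }
  Lk <- sqrt(nz)
  tau <- 0.95 / Lk
  sig <- 0.95 / Lk
  x <- numeric(n)
  xb <- x
  q <- numeric(length(yv))
  px <- matrix(0, g, g); py <- matrix(0, g, g)
  objTrace <- numeric(0)
  for (it in seq_len(maxIterations)) {
    q <- (q + sig * (as.numeric(W %*% xb) - yv)) / (1 + sig)
    gb <- gradOp(xb)
    px1 <- px + sig * gb$dx
    py1 <- py + sig * gb$dy
    mag <- pmax(1, sqrt(px1^2 + py1^2) / lambda)
    px <- px1 / mag
    py <- py1 / mag
    xOld <- x
    x <- x - tau * (as.numeric(Matrix::crossprod(W, q)) - divOp(px, py))
    x <- pmax(x, 0)
    if (any(!is.finite(x))) stop("Chambolle-Pock diverged (step size)")
    xb <- 2 * x - xOld
    if (it %% 10 == 0 || it == maxIterations) {
      r <- as.numeric(W %*% x) - yv
      gx <- gradOp(x)
      objTrace <- c(objTrace,
                    0.5 * sum(r^2) + lambda * sum(sqrt(gx$dx^2 + gx$dy^2)))
    }
    rel <- sqrt(sum((x - xOld)^2)) / max(sqrt(sum(xOld^2)), 1e-12)
    if (it > 10 && rel <= tol) break
  }
  structure(matrix(x, g, g), trace = objTrace, iterations = it)
}
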