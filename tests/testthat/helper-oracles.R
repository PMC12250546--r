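# Independent oracles and small shared fixtures, built in code.

# brute-force ray marching: line integral of a pixel image along the ray
# at angle theta and lateral offset t (same parameterization as the
# projector: ray direction (-sin, cos), offset along (cos, sin)), by
# nearest-pixel sampling with a fine step.
rayMarchOracle <- function(img, theta, t, step = 1e-3) {
  g <- nrow(img)
  h <- g / 2
  L <- sqrt(2) * g
  s <- seq(-L / 2, L / 2, by = step)
  px <- t * cos(theta) - s * sin(theta)
  py <- t * sin(theta) + s * cos(theta)
  ix <- floor(px + h) + 1
  iy <- floor(py + h) + 1
  ok <- ix >= 1 & ix <= g & iy >= 1 & iy <= g
  sum(img[cbind(iy[ok], ix[ok])]) * step
}

# proximal-gradient (ISTA with backtracking-free fixed step) solver for
# min 0.5*||Ax - b||^2 + C*||x||_1 ; step = 1/||A||^2
istaOracle <- function(A, b, C, iters = 20000) {
  Lc <- max(svd(A, nu = 0, nv = 0)$d)^2
  st <- 1 / Lc
  x <- numeric(ncol(A))
  soft <- function(z, tau) sign(z) * pmax(abs(z) - tau, 0)
  for (i in seq_len(iters)) {
    x <- soft(x - st * as.numeric(crossprod(A, A %*% x - b)), st * C)
  }
  list(x = x,
       value = 0.5 * sum((A %*% x - b)^2) + C * sum(abs(x)))
}

# independently coded global-statistics SSIM (sum formulas, population
# moments), for cross-checking imageSSIM
ssimOracle <- function(x, y, L = 1, k1 = 0.01, k2 = 0.03) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  mx <- sx / n; my <- sy / n
  vx <- sum(x^2) / n - mx^2
  vy <- sum(y^2) / n - my^2
  cxy <- sum(x * y) / n - mx * my
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# 4-connected component count of a logical mask
countComponents4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 ||
            p[2] > ncol(mask)) next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- cur
        stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
    }
  }
  cur
}

# small shared tomography fixture (memoised per test run)
smallTomoFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- 16L
      geom <- makeGeometry(8, c(0, pi), gridSize = g)
      A <- buildSystemMatrix(geom, g)
      dict <- buildDictionary(g, gammas = 0.15)
      cache <<- list(g = g, geom = geom, A = A, dict = dict,
                     cfg2 = levelSetConfig(grayLevels = c(0, 1)),
                     cfg3 = levelSetConfig(grayLevels = c(0, 0.5, 1)))
    }
    cache
  }
})
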