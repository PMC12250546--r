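#' Options for the OWL-QN solver
#'
#' @param memory number of L-BFGS curvature pairs kept (>= 1).
#' @param maxIterations iteration cap.
#' @param gradTol stop when the sup-norm of the pseudo-gradient falls to
#'   or below this.
#' @param fRelTol stop when the relative objective decrease falls to or
#'   below this.
#' @param armijoSigma sufficient-decrease constant of the backtracking
#'   line search.
#' @param backtrack step shrink factor in (0, 1).
#' @param verbose print per-iteration objective, pseudo-gradient norm,
#'   step and nnz.
#' @return list of validated options.
#' @export
owlqnOptions <- function(memory = 10L, maxIterations = 1000L,
                         gradTol = 1e-6, fRelTol = 1e-10,
                         armijoSigma = 1e-4, backtrack = 0.5,
                         verbose = FALSE) {
  stopifnot(memory >= 1, maxIterations >= 1, gradTol > 0, fRelTol > 0,
            armijoSigma > 0, armijoSigma < 1, backtrack > 0, backtrack < 1)
  list(memory = as.integer(memory),
       maxIterations = as.integer(maxIterations),
       gradTol = gradTol, fRelTol = fRelTol,
       armijoSigma = armijoSigma, backtrack = backtrack,
       verbose = isTRUE(verbose))
}

#' Pseudo-gradient of l(x) + C * ||x||_1
#'
#' The steepest one-sided descent direction of the l1-regularized
#' objective: for \eqn{x_i \ne 0} it is \eqn{g_i + C\,\mathrm{sign}(x_i)};
#' at \eqn{x_i = 0} it is \eqn{g_i + C} when \eqn{g_i < -C}, \eqn{g_i - C}
#' when \eqn{g_i > C}, and 0 otherwise.
#'
#' @param gradL gradient of the smooth part at \code{x}.
#' @param x current point, same length.
#' @param C nonnegative l1 weight.
#' @return pseudo-gradient vector.
#' @export
pseudoGradient <- function(gradL, x, C) {
  if (length(gradL) != length(x)) stop("gradL and x length mismatch")
  pg <- gradL + C * sign(x)
  z <- x == 0
  if (any(z)) {
    gz <- gradL[z]
    pz <- numeric(sum(z))
    lo <- gz < -C
    hi <- gz > C
    pz[lo] <- gz[lo] + C
    pz[hi] <- gz[hi] - C
    pg[z] <- pz
  }
  pg
}

#' Orthant projection
#'
#' Componentwise: keeps \code{x[i]} where \code{sign(x[i]) ==
#' sign(ref[i])} and zeroes it otherwise (with \code{sign(0) == 0}).
#'
#' @param x vector to project.
#' @param ref reference vector defining the orthant.
#' @return projected vector.
#' @export
orthantProject <- function(x, ref) {
  if (length(x) != length(ref)) stop("x and ref length mismatch")
  out <- x
  out[sign(x) != sign(ref)] <- 0
  out
}

#' Reference orthant direction
#'
#' \eqn{\xi_i = \mathrm{sign}(x_i)} where \eqn{x_i \ne 0}, else
#' \eqn{\mathrm{sign}(v_i)} with \eqn{v = -} pseudo-gradient.
#'
#' @param x current iterate.
#' @param v negative pseudo-gradient.
#' @return sign vector in \{-1, 0, 1\}.
#' @export
chooseOrthant <- function(x, v) {
  xi <- sign(x)
  z <- x == 0
  xi[z] <- sign(v[z])
  xi
}

# L-BFGS two-loop recursion: H*v from stored pairs (most recent last).
twoLoop <- function(v, S, Y, rho) {
  m <- length(S)
  if (m == 0L) return(v)
  a <- numeric(m)
  q <- v
  for (i in m:1) {
    a[i] <- rho[i] * sum(S[[i]] * q)
    q <- q - a[i] * Y[[i]]
  }
  ylast <- Y[[m]]; slast <- S[[m]]
  q <- q * (sum(slast * ylast) / sum(ylast * ylast))
  for (i in 1:m) {
    b <- rho[i] * sum(Y[[i]] * q)
    q <- q + (a[i] - b) * S[[i]]
  }
  q
}

#' Minimize l(x) + C * ||x||_1 with OWL-QN
#'
#' Orthant-wise limited-memory quasi-Newton descent: at each iteration the
#' pseudo-gradient is computed, an L-BFGS approximation of the inverse
#' Hessian of the smooth part is applied to its negative, the resulting
#' direction is projected onto the orthant of the steepest-descent
#' direction, and a backtracking Armijo line search over points projected
#' onto the reference orthant produces the next iterate. Coefficients
#' zeroed by projection stay exactly zero, so sparsity accumulates.
#'
#' @param fn smooth loss \eqn{l(x)} (the l1 term is added internally).
#' @param gr gradient of \code{fn}.
#' @param x0 start vector.
#' @param C nonnegative l1 weight (0 reduces to projected L-BFGS, and the
#'   projection is inert away from the axes).
#' @param options an \code{\link{owlqnOptions}} list.
#' @return list with elements \code{x}, \code{value} (final objective
#'   including the l1 term), \code{trace} (accepted objective values,
#'   starting at the initial point), \code{iterations},
#'   \code{converged} (one of \code{"gradient"}, \code{"ftol"},
#'   \code{"maxit"}, \code{"stagnation"}).
#' @examples
#' # soft-thresholding: min 0.5*(x-2)^2 + 1*|x| has minimum at x = 1
#' owlqnMinimize(function(x) 0.5 * (x - 2)^2, function(x) x - 2,
#'               0, C = 1)$x
#' @export
owlqnMinimize <- function(fn, gr, x0, C = 0, options = owlqnOptions()) {
  if (C < 0) stop("C must be >= 0")
  x <- as.numeric(x0)
  l <- fn(x)
  g <- as.numeric(gr(x))
  if (!is.finite(l) || any(!is.finite(g)))
    stop("loss or gradient not finite at the starting point")
  f <- l + C * sum(abs(x))
  trace <- f
  S <- list(); Y <- list(); rho <- numeric()
  status <- "maxit"
  opt <- options
  it <- 0L
  while (it < opt$maxIterations) {
    it <- it + 1L
    pg <- pseudoGradient(g, x, C)
    if (max(abs(pg)) <= opt$gradTol) { status <- "gradient"; break }
    v <- -pg
    p <- twoLoop(v, S, Y, rho)
    p <- orthantProject(p, v)
    if (sum(v * p) <= 0) {
      # not a descent direction for the pseudo-gradient: reset history
      S <- list(); Y <- list(); rho <- numeric()
      p <- orthantProject(v, v)
    }
    xi <- chooseOrthant(x, v)
    alpha <- 1
    accepted <- FALSE
    lNew <- NA_real_; xNew <- x
    while (alpha >= 1e-12) {
      xt <- orthantProject(x + alpha * p, xi)
      lt <- fn(xt)
      ft <- lt + C * sum(abs(xt))
      # Armijo on the pseudo-gradient: f(x') <= f(x) + sigma * pg'(x' - x)
      if (is.finite(ft) &&
          ft <= f + opt$armijoSigma * sum(pg * (xt - x))) {
        xNew <- xt; lNew <- lt; fNew <- ft
        accepted <- TRUE
        break
      }
      alpha <- alpha * opt$backtrack
    }
    if (!accepted) { status <- "stagnation"; break }
    gNew <- as.numeric(gr(xNew))
    s <- xNew - x
    yv <- gNew - g
    sy <- sum(s * yv)
    if (sy > 1e-12) {
      S[[length(S) + 1L]] <- s
      Y[[length(Y) + 1L]] <- yv
      rho <- c(rho, 1 / sy)
      if (length(S) > opt$memory) {
        S <- S[-1L]; Y <- Y[-1L]; rho <- rho[-1L]
      }
    }
    if (opt$verbose)
      message(sprintf("it %4d  f %.8e  |pg| %.3e  step %.2e  nnz %d",
                      it, fNew, max(abs(pg)), alpha, sum(xNew != 0)))
    relDf <- (f - fNew) / max(abs(f), 1e-300)
    x <- xNew; g <- gNew; f <- fNew
    trace <- c(trace, f)
    if (relDf <= opt$fRelTol) { status <- "ftol"; break }
  }
  list(x = x, value = f, trace = trace, iterations = it,
       converged = status)
}
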