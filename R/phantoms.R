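#' Synthetic piecewise-constant phantoms
#'
#' Generates the ground-truth test images for the simulation studies:
#' binary shapes of varying geometric difficulty (convex, annular,
#' disconnected, non-convex, letter-like) and a nested three-gray-level
#' object (shell / kernel / air topology). All shape parameters are in
#' normalized [0,1] x [0,1] domain coordinates; rasterization is by pixel
#' centers, so ground truth contains only the declared gray levels with no
#' anti-aliased edges. Generation is deterministic for a given spec and
#' seed.
#'
#' @param kind one of \code{"disc"}, \code{"annulus"}, \code{"two_blobs"},
#'   \code{"nonconvex_blob"}, \code{"letter"}.
#' @param gridSize image side in pixels.
#' @param grayLevels length-2 increasing numeric (background, foreground);
#'   defaults to c(0, 1).
#' @param params named list overriding shape defaults (see Details).
#' @param seed integer recorded with the phantom (generation itself is
#'   parametric and deterministic).
#' @details Shape defaults: \code{disc} r = 0.3 at the center;
#'   \code{annulus} outer 0.32 / inner 0.18; \code{two_blobs} two discs of
#'   radius 0.14 at (0.32, 0.36) and (0.68, 0.66);
#'   \code{nonconvex_blob} a star-shaped region with radial profile
#'   \eqn{r(\theta) = r_0 (1 + a \cos k\theta)}, defaults \eqn{r_0 =
#'   0.26}, \eqn{a = 0.22}, \eqn{k = 3}; \code{letter} a block "T" glyph.
#' @return \code{gridSize x gridSize} numeric matrix with values in
#'   \code{grayLevels}; attributes \code{kind}, \code{params}, \code{seed}.
#' @examples
#' p <- makeBinaryPhantom("disc", 32)
#' table(p)
#' @export
makeBinaryPhantom <- function(kind = c("disc", "annulus", "two_blobs",
                                       "nonconvex_blob", "letter"),
                              gridSize, grayLevels = c(0, 1),
                              params = list(), seed = NA_integer_) {
  kind <- match.arg(kind)
  if (length(grayLevels) != 2L || diff(grayLevels) <= 0)
    stop("binary phantoms need 2 increasing gray levels")
  g <- as.integer(gridSize)
  cc <- (seq_len(g) - 0.5) / g
  Y <- matrix(rep(cc, times = g), g, g)   # rows: y
  X <- matrix(rep(cc, each = g), g, g)    # cols: x
  def <- switch(kind,
    disc = list(center = c(0.5, 0.5), r = 0.3),
    annulus = list(center = c(0.5, 0.5), rOuter = 0.32, rInner = 0.18),
    two_blobs = list(c1 = c(0.32, 0.36), r1 = 0.14,
                     c2 = c(0.68, 0.66), r2 = 0.14),
    nonconvex_blob = list(center = c(0.5, 0.5), r0 = 0.26, amp = 0.22,
                          lobes = 3, rot = 0.4),
    letter = list())
  p <- utils::modifyList(def, params)
  inside <- switch(kind,
    disc = {
      checkFit(p$center, p$r)
      (X - p$center[1])^2 + (Y - p$center[2])^2 <= p$r^2
    },
    annulus = {
      checkFit(p$center, p$rOuter)
      if (p$rInner >= p$rOuter) stop("rInner must be < rOuter")
      d2 <- (X - p$center[1])^2 + (Y - p$center[2])^2
      d2 <= p$rOuter^2 & d2 > p$rInner^2
    },
    two_blobs = {
      checkFit(p$c1, p$r1); checkFit(p$c2, p$r2)
      if (sqrt(sum((p$c1 - p$c2)^2)) <= p$r1 + p$r2)
        stop("blobs overlap; they must form two components")
      ((X - p$c1[1])^2 + (Y - p$c1[2])^2 <= p$r1^2) |
        ((X - p$c2[1])^2 + (Y - p$c2[2])^2 <= p$r2^2)
    },
    nonconvex_blob = {
      checkFit(p$center, p$r0 * (1 + p$amp))
      dx <- X - p$center[1]; dy <- Y - p$center[2]
      th <- atan2(dy, dx)
      rb <- p$r0 * (1 + p$amp * cos(p$lobes * (th - p$rot)))
      dx^2 + dy^2 <= rb^2
    },
    letter = {
      # block "T": horizontal bar + vertical stem
      (X >= 0.2 & X <= 0.8 & Y >= 0.62 & Y <= 0.78) |
        (X >= 0.42 & X <= 0.58 & Y >= 0.2 & Y <= 0.78)
    })
  img <- matrix(grayLevels[1], g, g)
  img[inside] <- grayLevels[2]
  structure(img, kind = kind, params = p, seed = as.integer(seed))
}

checkFit <- function(center, r) {
  if (center[1] - r < 0 || center[1] + r > 1 ||
      center[2] - r < 0 || center[2] + r > 1)
    stop("shape exceeds the image domain")
  invisible(TRUE)
}

#' Nested three-gray-level phantom
#'
#' A disc of the middle gray level containing a strictly interior disc of
#' the highest level, on background \code{grayLevels[1]} — the shell /
#' kernel / air topology of a nut cross-section. Suitable for the
#' two-level-set (three-region) reconstruction model.
#'
#' @param gridSize image side in pixels.
#' @param grayLevels strictly increasing numeric of length 3.
#' @param params named list: \code{center}, outer radius \code{rOuter}
#'   (default 0.32), kernel radius \code{rInner} (default 0.17), kernel
#'   center offset \code{innerOffset} (default c(0, 0)).
#' @param seed integer recorded with the phantom.
#' @return \code{gridSize x gridSize} matrix with values in
#'   \code{grayLevels}.
#' @export
makeThreeLevelPhantom <- function(gridSize, grayLevels = c(0, 0.5, 1),
                                  params = list(), seed = NA_integer_) {
  if (length(grayLevels) != 3L || any(diff(grayLevels) <= 0))
    stop("three-level phantoms need 3 increasing gray levels")
  g <- as.integer(gridSize)
  p <- utils::modifyList(
    list(center = c(0.5, 0.5), rOuter = 0.32, rInner = 0.17,
         innerOffset = c(0, 0)), params)
  if (p$rInner + sqrt(sum(p$innerOffset^2)) >= p$rOuter)
    stop("inner region must be strictly inside the outer region")
  checkFit(p$center, p$rOuter)
  cc <- (seq_len(g) - 0.5) / g
  Y <- matrix(rep(cc, times = g), g, g)
  X <- matrix(rep(cc, each = g), g, g)
  d2o <- (X - p$center[1])^2 + (Y - p$center[2])^2
  ci <- p$center + p$innerOffset
  d2i <- (X - ci[1])^2 + (Y - ci[2])^2
  img <- matrix(grayLevels[1], g, g)
  img[d2o <= p$rOuter^2] <- grayLevels[2]
  img[d2i <= p$rInner^2] <- grayLevels[3]
  structure(img, kind = "nested_three_level", params = p,
            seed = as.integer(seed))
}

#' Add Gaussian noise to projection data
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' \eqn{\sigma = n \cdot \max(y)} — the relative noise-level convention of
#' the simulation studies (levels n of 0, 0.01, 0.05, 0.1). The level and
#' seed are recorded in the returned sinogram; \code{n = 0} returns the
#' input unchanged. The caller's RNG state is left untouched.
#'
#' @param y a \linkS4class{Sinogram}.
#' @param n relative noise level (>= 0).
#' @param seed integer seed for the noise realization.
#' @return a \linkS4class{Sinogram} with noisy values.
#' @export
addProjectionNoise <- function(y, n, seed = 1L) {
  stopifnot(is(y, "Sinogram"))
  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop("noise level n must be a nonnegative scalar")
  if (n == 0) return(y)
  v <- y@values
  sdev <- n * max(v)
  eta <- withSeed(as.integer(seed),
                  stats::rnorm(length(v), mean = 0, sd = sdev))
  new("Sinogram", values = v + matrix(eta, nrow(v), ncol(v)),
      geometry = y@geometry, noiseLevel = n, noiseSeed = as.integer(seed))
}

# run expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
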