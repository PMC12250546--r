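#' Create a parallel-beam scan geometry
#'
#' Angles are placed equally spaced on the half-open interval
#' \code{[angularRange[1], angularRange[2])}: the upper end is excluded so
#' that, e.g., 0 and \eqn{\pi} (redundant in parallel beam) are never both
#' sampled. With the default detector bank, \code{nDetectors} detectors at
#' unit pixel spacing cover the diagonal of a \code{gridSize}-pixel image.
#'
#' @param nProjections number of projection angles (>= 1).
#' @param angularRange numeric length-2, \code{c(theta_min, theta_max)} in
#'   radians with positive width.
#' @param nDetectors number of detector bins; default
#'   \code{ceiling(sqrt(2) * gridSize)} when \code{gridSize} is given.
#' @param detectorSpacing detector pitch in pixel units (default 1).
#' @param gridSize optional image side used to derive \code{nDetectors} and
#'   to check lateral coverage.
#' @return a \linkS4class{ScanGeometry}.
#' @examples
#' makeGeometry(4, c(0, pi), gridSize = 64)
#' @export
makeGeometry <- function(nProjections, angularRange, nDetectors = NULL,
                         detectorSpacing = 1, gridSize = NULL) {
  if (!is.numeric(nProjections) || length(nProjections) != 1L ||
      nProjections < 1)
    stop("nProjections must be a positive integer")
  nProjections <- as.integer(nProjections)
  if (length(angularRange) != 2L || diff(angularRange) <= 0)
    stop("angularRange must be c(min, max) with positive width")
  if (is.null(nDetectors)) {
    if (is.null(gridSize))
      stop("either nDetectors or gridSize must be given")
    nDetectors <- ceiling(sqrt(2) * gridSize)
  }
  if (nDetectors < 1) stop("nDetectors must be positive")
  if (!is.null(gridSize) &&
      nDetectors * detectorSpacing < sqrt(2) * gridSize)
    warning("detector bank does not cover the image diagonal; ",
            "rays will miss part of the image")
  width <- angularRange[2] - angularRange[1]
  th <- angularRange[1] + width * (seq_len(nProjections) - 1L) / nProjections
  th <- th %% (2 * pi)
  new("ScanGeometry",
      beamType = "parallel",
      angles = th,
      nDetectors = as.integer(nDetectors),
      detectorSpacing = as.numeric(detectorSpacing),
      angularRange = as.numeric(angularRange))
}

#' Detector lateral offsets (pixel units, centered on the rotation axis)
#' @keywords internal
#' @noRd
detectorOffsets <- function(geom) {
  n <- geom@nDetectors
  (seq_len(n) - (n + 1) / 2) * geom@detectorSpacing
}

# Exact intersection lengths of one ray with the pixels of a square grid
# centered at the origin (pixel size 1, side g). The ray is the line
# { t*n + s*d : s in R } with n = (cos th, sin th), d = (-sin th, cos th).
# Returns list(cols, lens) with 1-based column-major pixel indices.
siddonRay <- function(theta, t, g) {
  h <- g / 2
  nx <- cos(theta); ny <- sin(theta)
  dx <- -ny; dy <- nx
  px <- t * nx; py <- t * ny
  eps <- 1e-12
  # slab entry/exit
  smin <- -Inf; smax <- Inf
  if (abs(dx) > eps) {
    s1 <- (-h - px) / dx; s2 <- (h - px) / dx
    smin <- max(smin, min(s1, s2)); smax <- min(smax, max(s1, s2))
  } else if (px <= -h || px >= h) {
    return(list(cols = integer(), lens = numeric()))
  }
  if (abs(dy) > eps) {
    s1 <- (-h - py) / dy; s2 <- (h - py) / dy
    smin <- max(smin, min(s1, s2)); smax <- min(smax, max(s1, s2))
  } else if (py <= -h || py >= h) {
    return(list(cols = integer(), lens = numeric()))
  }
  if (smin >= smax) return(list(cols = integer(), lens = numeric()))
  planes <- -h + 0:g
  ss <- c(if (abs(dx) > eps) (planes - px) / dx,
          if (abs(dy) > eps) (planes - py) / dy)
  ss <- sort(unique(c(smin, smax, ss[ss > smin & ss < smax])))
  lens <- diff(ss)
  keep <- lens > 1e-12
  if (!any(keep)) return(list(cols = integer(), lens = numeric()))
  smid <- (ss[-length(ss)] + ss[-1]) / 2
  mx <- px + smid * dx
  my <- py + smid * dy
  ix <- pmin(pmax(floor(mx + h) + 1L, 1L), g)
  iy <- pmin(pmax(floor(my + h) + 1L, 1L), g)
  cols <- (ix - 1L) * g + iy
  list(cols = cols[keep], lens = lens[keep])
}

#' Build the sparse system matrix for a geometry and pixel grid
#'
#' Traverses every ray through the square pixel grid (Siddon-style exact
#' ray--pixel intersection lengths) and assembles the sparse projection
#' operator \eqn{A} with one row per (angle, detector) pair, angle-major.
#' Pixels are indexed in R column-major order of a \code{gridSize x
#' gridSize} matrix whose rows are the y axis and columns the x axis, with
#' the image square centered on the rotation axis. Rays that miss the image
#' give all-zero rows but are retained so the row index always equals
#' \code{(angle - 1) * nDetectors + detector}.
#'
#' @param geom a \linkS4class{ScanGeometry}.
#' @param gridSize side of the square image grid (>= 2).
#' @return a \linkS4class{SystemMatrix}.
#' @examples
#' A <- buildSystemMatrix(makeGeometry(2, c(0, pi), gridSize = 8), 8)
#' @export
buildSystemMatrix <- function(geom, gridSize) {
  stopifnot(is(geom, "ScanGeometry"))
  if (gridSize < 2) stop("gridSize must be >= 2")
  g <- as.integer(gridSize)
  offs <- detectorOffsets(geom)
  nd <- geom@nDetectors
  nray <- length(geom@angles) * nd
  ri <- vector("list", nray)
  ci <- vector("list", nray)
  xs <- vector("list", nray)
  r <- 0L
  for (a in seq_along(geom@angles)) {
    th <- geom@angles[a]
    for (d in seq_len(nd)) {
      r <- r + 1L
      seg <- siddonRay(th, offs[d], g)
      if (length(seg$cols)) {
        # duplicate indices can occur when a midpoint is clamped; aggregate
        ci[[r]] <- seg$cols
        xs[[r]] <- seg$lens
        ri[[r]] <- rep.int(r, length(seg$cols))
      }
    }
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ri), j = unlist(ci), x = unlist(xs),
    dims = c(nray, g * g), repr = "C")
  A <- Matrix::drop0(A)
  new("SystemMatrix", weights = A, geometry = geom, gridSize = g)
}

#' Forward-project an image
#'
#' Computes the sparse matrix--vector product \eqn{y = Ax} and wraps it as
#' a \linkS4class{Sinogram}.
#'
#' @param A a \linkS4class{SystemMatrix}.
#' @param image numeric matrix (\code{gridSize x gridSize}) or vector of
#'   length \code{gridSize^2} in column-major order.
#' @return a \linkS4class{Sinogram}.
#' @export
forwardProject <- function(A, image) {
  stopifnot(is(A, "SystemMatrix"))
  x <- as.numeric(image)
  if (length(x) != ncol(A@weights))
    stop("image length does not match system matrix columns")
  y <- as.numeric(A@weights %*% x)
  g <- A@geometry
  new("Sinogram",
      values = matrix(y, nrow = length(g@angles), ncol = g@nDetectors,
                      byrow = TRUE),
      geometry = g)
}

#' Flatten a sinogram to the ray-major vector matching the system matrix
#' @param y a \linkS4class{Sinogram} or numeric matrix (angles x detectors).
#' @return numeric vector ordered angle-major.
#' @export
sinogramVector <- function(y) {
  v <- if (is(y, "Sinogram")) y@values else y
  as.numeric(t(v))
}
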