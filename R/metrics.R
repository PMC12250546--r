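#' Mean squared error between two images
#'
#' \eqn{\mathrm{MSE} = \frac{1}{MN}\sum_{ij}(x_{ij} - x^*_{ij})^2}.
#'
#' @param x,xref numeric matrices of equal shape.
#' @return nonnegative scalar.
#' @export
imageMSE <- function(x, xref) {
  if (!identical(dim(x), dim(xref)))
    stop("images must have identical dimensions")
  mean((x - xref)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' \eqn{10 \log_{10}(\mathrm{MAX}^2 / \mathrm{MSE})}. Identical images
#' (MSE = 0) give \code{Inf}.
#'
#' @param x,xref numeric matrices of equal shape.
#' @param maxValue the maximum possible pixel value MAX (> 0); 1 for the
#'   binary and unit-range discrete models.
#' @return PSNR in dB.
#' @export
imagePSNR <- function(x, xref, maxValue = 1) {
  if (maxValue <= 0) stop("maxValue must be > 0")
  m <- imageMSE(x, xref)
  if (m == 0) return(Inf)
  10 * log10(maxValue^2 / m)
}

#' Structural similarity index
#'
#' Global-statistics SSIM,
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_x\mu_{x^*} + c_1)(2\sigma_{x,x^*} +
#' c_2)}{(\mu_x^2 + \mu_{x^*}^2 + c_1)(\sigma_x^2 + \sigma_{x^*}^2 +
#' c_2)}}
#' with population moments over the whole image and stabilizers
#' \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2}. The default is the single
#' global evaluation; \code{windowSize} switches to the mean of local SSIM
#' over non-overlapping square windows for cross-checking against
#' windowed implementations.
#'
#' @param x,xref numeric matrices of equal shape.
#' @param L dynamic range of the pixel values (default 1).
#' @param k1,k2 stabilization factors (defaults 0.01, 0.03).
#' @param windowSize \code{NULL} (global, default) or window side in
#'   pixels.
#' @return scalar in [-1, 1].
#' @export
imageSSIM <- function(x, xref, L = 1, k1 = 0.01, k2 = 0.03,
                      windowSize = NULL) {
  if (!identical(dim(x), dim(xref)))
    stop("images must have identical dimensions")
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  ssim1 <- function(a, b) {
    n <- length(a)
    ma <- mean(a); mb <- mean(b)
    va <- sum((a - ma)^2) / n
    vb <- sum((b - mb)^2) / n
    cab <- sum((a - ma) * (b - mb)) / n
    ((2 * ma * mb + c1) * (2 * cab + c2)) /
      ((ma^2 + mb^2 + c1) * (va + vb + c2))
  }
  if (is.null(windowSize)) return(ssim1(x, xref))
  w <- as.integer(windowSize)
  stopifnot(w >= 2, w <= min(dim(x)))
  si <- seq(1, nrow(x) - w + 1, by = w)
  sj <- seq(1, ncol(x) - w + 1, by = w)
  vals <- outer(si, sj, Vectorize(function(i, j)
    ssim1(x[i:(i + w - 1), j:(j + w - 1)],
          xref[i:(i + w - 1), j:(j + w - 1)])))
  mean(vals)
}

#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} between the foreground masks of
#' \code{truth} and \code{recon} at the gray level \code{level}. When both
#' masks are empty the coefficient is defined as 1.
#'
#' @param truth,recon label images restricted to a common discrete
#'   gray-level set.
#' @param level the gray level defining the foreground mask.
#' @param grayLevels optional full gray-level set; if given, \code{level}
#'   is checked against it.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(truth, recon, level = NULL,
                            grayLevels = NULL) {
  if (!identical(dim(truth), dim(recon)))
    stop("images must have identical dimensions")
  if (is.null(level)) {
    lv <- if (is.null(grayLevels)) sort(unique(as.numeric(truth)))
          else grayLevels
    level <- max(lv)
  }
  if (!is.null(grayLevels) && !level %in% grayLevels)
    stop("level is not in the gray-level set")
  A <- truth == level
  B <- recon == level
  denom <- sum(A) + sum(B)
  if (denom == 0) return(1)
  2 * sum(A & B) / denom
}

#' Full metric report between a reconstruction and ground truth
#'
#' @param truth ground-truth discrete image.
#' @param recon reconstructed (quantized) image.
#' @param grayLevels the discrete gray-level set; Dice is reported for
#'   every level above the background (first) level.
#' @param maxValue MAX for PSNR (default: range of grayLevels).
#' @return list with \code{mse}, \code{psnr}, \code{ssim}, and named
#'   \code{dice} per foreground level.
#' @export
metricReport <- function(truth, recon, grayLevels = sort(unique(as.numeric(truth))),
                         maxValue = diff(range(grayLevels))) {
  fg <- grayLevels[-1]
  dice <- vapply(fg, function(lv)
    diceCoefficient(truth, recon, lv, grayLevels), numeric(1))
  names(dice) <- as.character(fg)
  list(mse = imageMSE(recon, truth),
       psnr = imagePSNR(recon, truth, maxValue),
       ssim = imageSSIM(recon, truth, L = maxValue),
       dice = dice)
}
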