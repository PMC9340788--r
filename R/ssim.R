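# Structural similarity: single-scale SSIM with an analytic gradient (used
# inside the training objective) and multi-scale SSIM (used as a quality
# metric). Local statistics use the standard 11x11 Gaussian window with
# sigma 1.5 and stabilizing constants C1 = (0.01 L)^2, C2 = (0.03 L)^2.
#
# The loss-side SSIM uses "valid" windows (no padding), so its adjoint is
# an exact zero-padded full correlation and gradients check against finite
# differences. The metric-side MS-SSIM uses reflect padding so that the
# coarse dyadic scales of small images remain defined.

gauss_kernel <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

SSIM_WIN <- 11
SSIM_SIGMA <- 1.5

ssim_stats <- function(x, y, k, mode, dataRange = 1) {
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  mx <- cpp_sepfilter(x, k, mode);  my <- cpp_sepfilter(y, k, mode)
  mxx <- cpp_sepfilter(x * x, k, mode)
  myy <- cpp_sepfilter(y * y, k, mode)
  mxy <- cpp_sepfilter(x * y, k, mode)
  vx <- mxx - mx * mx; vy <- myy - my * my; vxy <- mxy - mx * my
  A1 <- 2 * mx * my + C1; A2 <- 2 * vxy + C2
  B1 <- mx * mx + my * my + C1; B2 <- vx + vy + C2
  list(mx = mx, my = my, vx = vx, vy = vy, vxy = vxy,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       S = (A1 * A2) / (B1 * B2), cs = A2 / B2)
}

#' Structural similarity between two images
#'
#' Mean single-scale SSIM over valid 11x11 Gaussian windows (sigma 1.5),
#' data range 1.
#'
#' @param x,y numeric matrices of one shape, values on [0, dataRange];
#'   both dimensions must be at least 11
#' @param dataRange dynamic range of the data (default 1)
#' @return scalar mean SSIM (1 for identical images)
#' @export
ssimIndex <- function(x, y, dataRange = 1) {
  if (!identical(dim(x), dim(y))) stop("x and y must share one shape")
  if (min(dim(x)) < SSIM_WIN)
    stop("images must be at least ", SSIM_WIN, " pixels in each dimension")
  mean(ssim_stats(x, y, gauss_kernel(), 2L, dataRange)$S)
}

# mean SSIM and its gradient with respect to x (y fixed)
ssim_with_grad <- function(x, y, dataRange = 1) {
  k <- gauss_kernel()
  st <- ssim_stats(x, y, k, 2L, dataRange)
  v <- st$B1 * st$B2
  N <- length(st$S)
  # partials of the per-window score wrt the filtered statistics of x
  d_mu <- 2 * st$my * (st$A2 - st$A1) / v +
    2 * st$mx * st$S * (1 / st$B2 - 1 / st$B1)
  d_mxx <- -st$S / st$B2
  d_mxy <- 2 * st$A1 / v
  g <- cpp_sepfilter(d_mu, k, 3L) +
    2 * x * cpp_sepfilter(d_mxx, k, 3L) +
    y * cpp_sepfilter(d_mxy, k, 3L)
  list(value = mean(st$S), grad = g / N)
}

pool2 <- function(x) {
  # 2x2 average pooling (truncating an odd trailing row/column)
  h <- 2 * (nrow(x) %/% 2); w <- 2 * (ncol(x) %/% 2)
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (x[seq(1, h, 2), seq(1, w, 2)] + x[seq(2, h, 2), seq(1, w, 2)] +
          x[seq(1, h, 2), seq(2, w, 2)] + x[seq(2, h, 2), seq(2, w, 2)])
}

MSSSIM_WEIGHTS <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

#' Multi-scale structural similarity between two images
#'
#' Five dyadic scales with the standard exponents (0.0448, 0.2856, 0.3001,
#' 0.2363, 0.1333): the contrast-structure term at every scale, the
#' luminance term at the coarsest. Filtering uses reflect padding and
#' scales are reduced by 2x2 average pooling, so images down to 32 pixels
#' per side are supported. Negative contrast-structure means are clamped
#' at zero before the geometric combination.
#'
#' @param x,y numeric matrices of one shape, min dimension >= 32
#' @param dataRange dynamic range of the data (default 1)
#' @return scalar MS-SSIM in [0,1] for non-negative component means
#' @export
msssimIndex <- function(x, y, dataRange = 1) {
  if (!identical(dim(x), dim(y))) stop("x and y must share one shape")
  if (min(dim(x)) < 32)
    stop("MS-SSIM needs images of at least 32 pixels per side ",
         "(5 dyadic scales)")
  k <- gauss_kernel()
  val <- 1
  for (s in seq_along(MSSSIM_WEIGHTS)) {
    st <- ssim_stats(x, y, k, 1L, dataRange)
    if (s < length(MSSSIM_WEIGHTS)) {
      val <- val * max(mean(st$cs), 0)^MSSSIM_WEIGHTS[s]
      x <- pool2(x); y <- pool2(y)
    } else {
      val <- val * max(mean(st$S), 0)^MSSSIM_WEIGHTS[s]
    }
  }
  val
}
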