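# Inference-time fusion of disentangled features and YCbCr color handling.

check_same_shape <- function(A, B, what = "feature maps") {
  if (!identical(dim(A), dim(B))) stop(what, " must share one shape")
}

#' Addition strategy for complementary features
#'
#' C_f = C1 + C2 elementwise; combines all unique information of both
#' modalities directly.
#'
#' @param C1,C2 H x W x V feature arrays of one shape
#' @return fused feature array C_f
#' @export
fuseComplementaryAdd <- function(C1, C2) {
  C1 <- as_feature(C1, "C1"); C2 <- as_feature(C2, "C2")
  check_same_shape(C1, C2)
  C1 + C2
}

#' Max-selection strategy for complementary features
#'
#' Elementwise maximum, preserving the features of higher magnitude.
#' Encoder features are non-negative (final ReLU), so value-max and
#' magnitude-max coincide.
#'
#' @param C1,C2 H x W x V feature arrays of one shape
#' @return fused feature array C_f with C_f >= C1 and C_f >= C2
#' @export
fuseComplementaryMax <- function(C1, C2) {
  C1 <- as_feature(C1, "C1"); C2 <- as_feature(C2, "C2")
  check_same_shape(C1, C2)
  pmax(C1, C2)
}

#' L1-norm (activity-weighted) strategy for complementary features
#'
#' The per-position channel L1 norm is the activity level measurement
#' A_*(x,y); the fused feature is the activity-weighted convex combination
#' C_f(x,y) = mu1 C1(x,y) + mu2 C2(x,y) with mu1 = A1/(A1+A2) and
#' mu2 = 1 - mu1. Where both activities are zero both features vanish, so
#' mu1 = mu2 = 0.5 is used to avoid 0/0.
#'
#' @param C1,C2 H x W x V feature arrays of one shape
#' @return fused feature array C_f
#' @export
fuseComplementaryL1 <- function(C1, C2) {
  C1 <- as_feature(C1, "C1"); C2 <- as_feature(C2, "C2")
  check_same_shape(C1, C2)
  A1 <- channelL1Map(C1); A2 <- channelL1Map(C2)
  tot <- A1 + A2
  mu1 <- ifelse(tot > 0, A1 / tot, 0.5)
  V <- dim(C1)[3]
  array(rep(mu1, V), dim(C1)) * C1 + array(rep(1 - mu1, V), dim(C1)) * C2
}

#' Average strategy for redundant features
#'
#' R_f = (R1 + R2) / 2. The redundant features live in a common space
#' (shared encoder), so a simple symmetric average suffices.
#'
#' @param R1,R2 H x W x V feature arrays of one shape
#' @return fused feature array R_f
#' @export
fuseRedundant <- function(R1, R2) {
  R1 <- as_feature(R1, "R1"); R2 <- as_feature(R2, "R2")
  check_same_shape(R1, R2)
  (R1 + R2) / 2
}

fuse_strategy <- function(C1, C2, strategy) {
  switch(strategy,
         add = fuseComplementaryAdd(C1, C2),
         max = fuseComplementaryMax(C1, C2),
         l1 = fuseComplementaryL1(C1, C2),
         stop("unknown fusion strategy '", strategy,
              "' (expected add, max or l1)"))
}

#' Fuse a co-registered grayscale image pair
#'
#' Full inference pipeline: encode both images
#' (\code{\link{encodePair}}), fuse the complementary features with the
#' chosen strategy and the redundant features by averaging, then decode
#' I_f = De_S(C_f + R_f). The network is fully convolutional, so whole
#' images of any size >= 3 are fused without tiling; batch-normalization
#' uses the stored running statistics (evaluation mode).
#'
#' @param model a trained \code{\linkS4class{FusionModel}}
#' @param I1,I2 co-registered images, matrices in [0,1] of one shape
#' @param strategy complementary fusion strategy: "add", "max" or "l1"
#' @return the fused image, a matrix in [0,1] of the input shape
#' @export
fuseImages <- function(model, I1, I2, strategy = c("add", "max", "l1")) {
  strategy <- match.arg(strategy)
  if (!is(model, "FusionModel")) stop("model must be a FusionModel")
  f <- encodePair(model, I1, I2)
  decodeFeatures(model, fuse_strategy(f$C1, f$C2, strategy) +
                   fuseRedundant(f$R1, f$R2))
}

# ---- YCbCr (ITU-R BT.601 full-range / JPEG convention) ------------------

#' RGB to full-range YCbCr conversion
#'
#' ITU-R BT.601 full-range (JPEG) conversion on [0,1] channels:
#' luminance Y = 0.299 R + 0.587 G + 0.114 B; chrominance offsets 0.5.
#'
#' @param rgb H x W x 3 array with values in [0,1]
#' @return H x W x 3 array with channels Y, Cb, Cr in [0,1]
#' @export
rgbToYcbcr <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop("rgb must be an H x W x 3 array")
  R <- rgb[, , 1]; G <- rgb[, , 2]; B <- rgb[, , 3]
  Y <- 0.299 * R + 0.587 * G + 0.114 * B
  Cb <- -0.168736 * R - 0.331264 * G + 0.5 * B + 0.5
  Cr <- 0.5 * R - 0.418688 * G - 0.081312 * B + 0.5
  out <- array(0, c(dim(Y), 3))
  out[, , 1] <- Y; out[, , 2] <- Cb; out[, , 3] <- Cr
  out
}

#' @describeIn rgbToYcbcr inverse conversion, clipped to [0,1]
#' @param ycbcr H x W x 3 array with channels Y, Cb, Cr
#' @export
ycbcrToRgb <- function(ycbcr) {
  if (length(dim(ycbcr)) != 3 || dim(ycbcr)[3] != 3)
    stop("ycbcr must be an H x W x 3 array")
  Y <- ycbcr[, , 1]; Cb <- ycbcr[, , 2] - 0.5; Cr <- ycbcr[, , 3] - 0.5
  out <- array(0, dim(ycbcr))
  out[, , 1] <- Y + 1.402 * Cr
  out[, , 2] <- Y - 0.344136 * Cb - 0.714136 * Cr
  out[, , 3] <- Y + 1.772 * Cb
  pmin(pmax(out, 0), 1)
}

#' Fuse a grayscale image with a pseudo-color modality
#'
#' The RGB image (e.g. a pseudo-colored PET display) is converted to
#' full-range YCbCr; its luminance is fused with the grayscale image
#' through the network, and the fused luminance is recombined with the
#' original Cb/Cr chrominance before inverse conversion. Chrominance is
#' carried over unfused.
#'
#' @param model a trained \code{\linkS4class{FusionModel}}
#' @param gray1 grayscale image, matrix in [0,1]
#' @param color2 RGB image, H x W x 3 array in [0,1], same spatial size
#' @param strategy complementary fusion strategy: "add", "max" or "l1"
#' @return fused RGB image, H x W x 3 array in [0,1]
#' @export
fuseColor <- function(model, gray1, color2,
                      strategy = c("add", "max", "l1")) {
  strategy <- match.arg(strategy)
  if (length(dim(color2)) != 3 || dim(color2)[3] < 3)
    stop("color2 must be an H x W x 3 RGB array")
  if (!identical(dim(gray1), dim(color2)[1:2]))
    stop("gray1 and color2 must share one spatial size")
  ycc <- rgbToYcbcr(color2[, , 1:3])
  fusedY <- fuseImages(model, gray1, pmin(pmax(ycc[, , 1], 0), 1), strategy)
  ycc[, , 1] <- fusedY
  ycbcrToRgb(ycc)
}
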