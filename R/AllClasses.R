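#' defusion: disentangled-representation multi-modal brain image fusion
#'
#' A three-branch convolutional auto-encoder separates each image of a
#' co-registered multi-modal pair into complementary (modality-unique)
#' features and redundant (shared-structure) features. Training combines an
#' MSE + SSIM reconstruction objective with a redundant consistency
#' constraint and a complementary group-lasso penalty whose per-position
#' weights adapt to local feature importance through a similarity-steered
#' sigmoid. At inference the complementary features of the two images are
#' fused (add / max / activity-weighted L1), the redundant features are
#' averaged, and the shared decoder produces the fused image.
#'
#' @useDynLib defusion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats runif rnorm sd cor var aggregate setNames
#' @importFrom utils modifyList write.csv read.csv
#' @keywords internal
"_PACKAGE"

setClassUnion("ArrayOrNULL", c("array", "NULL"))

#' Network architecture configuration
#'
#' Describes the shared architecture of the three encoders and the decoder:
#' three 3x3 stride-1 convolution blocks with size-preserving padding.
#' The encoder channel path is \code{inChannels -> baseChannels ->
#' baseChannels -> outChannels} (default 1 -> 64 -> 64 -> 128) and the
#' decoder mirrors it back to one channel. Smaller channel counts are
#' supported for desk-scale experiments.
#'
#' @slot inChannels number of input image channels (1 for grayscale)
#' @slot baseChannels width of the two inner convolution blocks
#' @slot outChannels number of feature channels V at the encoder output
#' @slot kernelSize convolution kernel size; fixed at 3
#' @slot stride convolution stride; fixed at 1
#' @slot padding spatial padding; fixed at 1 so feature maps keep the
#'   image's spatial size (features must be added and decoded back)
#' @slot useVggInit whether \code{\link{initFromVGG}} should be applied
#' @export
setClass("NetConfig", representation(
  inChannels = "numeric", baseChannels = "numeric", outChannels = "numeric",
  kernelSize = "numeric", stride = "numeric", padding = "numeric",
  useVggInit = "logical"
))

setValidity("NetConfig", function(object) {
  msg <- character()
  for (s in c("inChannels", "baseChannels", "outChannels")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v))
      msg <- c(msg, sprintf("%s must be a positive integer", s))
  }
  if (object@kernelSize != 3) msg <- c(msg, "kernelSize must be 3")
  if (object@stride != 1) msg <- c(msg, "stride must be 1")
  if (object@padding != 1) msg <- c(msg, "padding must be 1 (size-preserving)")
  if (length(msg)) msg else TRUE
})

#' @describeIn NetConfig constructor with the standard-architecture defaults
#' @param inChannels,baseChannels,outChannels,useVggInit see slots
#' @return a validated \code{NetConfig}
#' @export
netConfig <- function(inChannels = 1, baseChannels = 64, outChannels = 128,
                      useVggInit = FALSE) {
  new("NetConfig", inChannels = inChannels, baseChannels = baseChannels,
      outChannels = outChannels, kernelSize = 3, stride = 1, padding = 1,
      useVggInit = useVggInit)
}

setMethod("show", "NetConfig", function(object) {
  cat(sprintf("NetConfig: %d -> %d -> %d -> %d, 3x3 conv stride 1 pad 1%s\n",
              object@inChannels, object@baseChannels, object@baseChannels,
              object@outChannels,
              if (object@useVggInit) ", VGG init" else ""))
})

#' Loss configuration
#'
#' Weights and numerical settings of the training objective
#' \code{total = lRec + lambdaR * lR + lambdaC * lC} with
#' \code{lRec = lambdaSsim * lSsim + lMse}.
#'
#' @slot lambdaSsim weight of the SSIM reconstruction term (default 1000)
#' @slot lambdaR weight of the redundant consistency term (default 10)
#' @slot lambdaC weight of the complementary group-lasso penalty (default 10)
#' @slot blockRadius radius r of the (2r+1)x(2r+1) block over which local
#'   feature importance is averaged (default 1, i.e. a 3x3 block)
#' @slot similarityEpsilon floor for the squared cosine similarity in the
#'   sigmoid steepness k = 1/max(r^2, eps); bounds k and keeps gradients
#'   finite (default 1e-4, so k <= 1e4)
#' @slot detachWeights treat the penalty weights as constants during
#'   backpropagation (default TRUE)
#' @slot lcNormalization "sum" (default) accumulates the group-lasso
#'   penalty over all spatial positions; "mean" divides by
#'   H*W. The sum keeps the per-position penalty strong enough to drive
#'   unimportant feature groups to exact zero — the filtering behaviour
#'   the penalty exists for — at the default lambdaC
#' @slot flipSign use the alternative sign convention
#'   \code{omega1 = 1/(1 + exp(k (phi2 - phi1)))} in which the more
#'   important feature receives the LARGER penalty weight; the default
#'   (FALSE) penalises the less important feature, which is the behaviour
#'   the method's weighting narrative describes
#' @export
setClass("LossConfig", representation(
  lambdaSsim = "numeric", lambdaR = "numeric", lambdaC = "numeric",
  blockRadius = "numeric", similarityEpsilon = "numeric",
  detachWeights = "logical", flipSign = "logical",
  lcNormalization = "character"
))

setValidity("LossConfig", function(object) {
  msg <- character()
  if (object@lambdaSsim < 0 || object@lambdaR < 0 || object@lambdaC < 0)
    msg <- c(msg, "all lambda weights must be >= 0")
  if (object@blockRadius < 0 || object@blockRadius != round(object@blockRadius))
    msg <- c(msg, "blockRadius must be a non-negative integer")
  if (object@similarityEpsilon <= 0)
    msg <- c(msg, "similarityEpsilon must be > 0")
  if (!object@lcNormalization %in% c("sum", "mean"))
    msg <- c(msg, "lcNormalization must be 'sum' or 'mean'")
  if (length(msg)) msg else TRUE
})

#' @describeIn LossConfig constructor with the standard defaults
#' @param lambdaSsim,lambdaR,lambdaC,blockRadius,similarityEpsilon,detachWeights,flipSign
#'   see slots
#' @return a validated \code{LossConfig}
#' @export
lossConfig <- function(lambdaSsim = 1000, lambdaR = 10, lambdaC = 10,
                       blockRadius = 1, similarityEpsilon = 1e-4,
                       detachWeights = TRUE, flipSign = FALSE,
                       lcNormalization = c("sum", "mean")) {
  new("LossConfig", lambdaSsim = lambdaSsim, lambdaR = lambdaR,
      lambdaC = lambdaC, blockRadius = blockRadius,
      similarityEpsilon = similarityEpsilon, detachWeights = detachWeights,
      flipSign = flipSign,
      lcNormalization = match.arg(lcNormalization))
}

setMethod("show", "LossConfig", function(object) {
  cat(sprintf(
    "LossConfig: lambdaSsim=%g lambdaR=%g lambdaC=%g r=%d eps=%g%s%s\n",
    object@lambdaSsim, object@lambdaR, object@lambdaC, object@blockRadius,
    object@similarityEpsilon,
    if (object@detachWeights) " (weights detached)" else "",
    if (object@flipSign) " [flipped sign]" else ""))
})

#' Training configuration
#'
#' @slot batchSize patches per gradient step (default 8)
#' @slot learningRate Adam step size (default 1e-4)
#' @slot patchSize side of the square random crops (default 120)
#' @slot nFolds folds of the k-fold verification experiment (default 10)
#' @slot iterations number of gradient steps (default 10000)
#' @slot seed RNG seed for init, batching and augmentation
#' @slot useLc include the complementary group-lasso penalty in the
#'   objective (FALSE reproduces the ablated model)
#' @slot lossConfig a \code{\link{LossConfig}}
#' @slot netConfig a \code{\link{NetConfig}}
#' @export
setClass("TrainConfig", representation(
  batchSize = "numeric", learningRate = "numeric", patchSize = "numeric",
  nFolds = "numeric", iterations = "numeric", seed = "numeric",
  useLc = "logical", lossConfig = "LossConfig", netConfig = "NetConfig"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@patchSize < 3) msg <- c(msg, "patchSize must be >= 3")
  if (object@nFolds < 2) msg <- c(msg, "nFolds must be >= 2")
  if (object@iterations < 1) msg <- c(msg, "iterations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainConfig constructor with the reference protocol defaults
#' @param batchSize,learningRate,patchSize,nFolds,iterations,seed,useLc,lossConfig,netConfig
#'   see slots
#' @return a validated \code{TrainConfig}
#' @export
trainConfig <- function(batchSize = 8, learningRate = 1e-4, patchSize = 120,
                        nFolds = 10, iterations = 10000, seed = 1,
                        useLc = TRUE, lossConfig = defusion::lossConfig(),
                        netConfig = defusion::netConfig()) {
  new("TrainConfig", batchSize = batchSize, learningRate = learningRate,
      patchSize = patchSize, nFolds = nFolds, iterations = iterations,
      seed = seed, useLc = useLc, lossConfig = lossConfig,
      netConfig = netConfig)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: batch=%d lr=%g patch=%d folds=%d iters=%d seed=%d useLc=%s\n",
    object@batchSize, object@learningRate, object@patchSize, object@nFolds,
    object@iterations, object@seed, object@useLc))
  show(object@lossConfig); show(object@netConfig)
})

#' Three-branch fusion auto-encoder
#'
#' Holds the two complementary encoders (one per modality), the shared
#' redundant encoder and the shared decoder, each a list of three
#' convolution blocks with optional batch-normalization state. The
#' redundant encoder and the decoder each carry exactly one parameter set
#' used for both modalities.
#'
#' @slot encC1,encC2 complementary encoders for modality 1 / 2
#' @slot encR shared redundant encoder
#' @slot dec shared decoder (sigmoid output, values in [0,1])
#' @slot config the \code{\link{NetConfig}} the networks were built from
#' @slot trained whether the model went through \code{\link{trainFusionModel}}
#' @slot iterations gradient steps performed so far
#' @export
setClass("FusionModel", representation(
  encC1 = "list", encC2 = "list", encR = "list", dec = "list",
  config = "NetConfig", trained = "logical", iterations = "numeric"
))

setMethod("show", "FusionModel", function(object) {
  np <- function(net) sum(vapply(net, function(l) {
    length(l$W) + length(l$b) + if (is.null(l$bn)) 0 else 2 * length(l$bn$gamma)
  }, numeric(1)))
  cat(sprintf(
    "FusionModel (%s, %d iterations)\n  En_C1/En_C2/En_R: %d params each, De_S: %d params\n",
    if (object@trained) "trained" else "untrained", object@iterations,
    np(object@encC1), np(object@dec)))
  show(object@config)
})

#' Scalar components of the training objective
#'
#' @slot lMse summed mean-squared reconstruction error of the four
#'   decode targets (self- and cross-reconstructions)
#' @slot lSsim summed (1 - SSIM) of the same four pairs
#' @slot lRec \code{lambdaSsim * lSsim + lMse}
#' @slot lR redundant consistency: mean absolute difference of the two
#'   decoded redundant features
#' @slot lC complementary group-lasso penalty
#' @slot total \code{lRec + lambdaR * lR + lambdaC * lC}
#' @export
setClass("LossBreakdown", representation(
  lMse = "numeric", lSsim = "numeric", lRec = "numeric",
  lR = "numeric", lC = "numeric", total = "numeric"
))

setValidity("LossBreakdown", function(object) {
  v <- lossComponents(object)
  if (any(!is.finite(v)))
    return(paste("non-finite loss component:",
                 paste(names(v)[!is.finite(v)], collapse = ", ")))
  if (any(v < -1e-9))
    return(paste("negative loss component:",
                 paste(names(v)[v < 0], collapse = ", ")))
  TRUE
})

#' @describeIn LossBreakdown all components as a named numeric vector
#' @param object a \code{LossBreakdown}
#' @export
lossComponents <- function(object) {
  c(lMse = object@lMse, lSsim = object@lSsim, lRec = object@lRec,
    lR = object@lR, lC = object@lC, total = object@total)
}

setMethod("show", "LossBreakdown", function(object) {
  v <- lossComponents(object)
  cat("LossBreakdown:", paste(sprintf("%s=%.6g", names(v), v),
                              collapse = " "), "\n")
})

#' Synthetic co-registered modality pair with known decomposition
#'
#' The generator composes each modality from a shared anatomical structure
#' S plus a modality-unique component: \code{I1 = clip(a1 S + b1 U1)} adds
#' band-limited texture (MRI-like soft-tissue detail), \code{I2 =
#' clip(a2 S + b2 U2)} adds dense bright blobs (CT-like structure). The
#' ground-truth decomposition is stored so disentanglement can be measured.
#'
#' @slot I1,I2 the two observed modality images, matrices in [0,1]
#' @slot shared ground-truth common structure S
#' @slot unique1,unique2 ground-truth modality-unique components U1, U2
#' @slot color2 optional RGB companion of I2 (H x W x 3 array) mimicking a
#'   pseudo-colored PET display, or NULL
#' @slot seed the seed this pair was generated from
#' @slot params generator parameters, including the mixing coefficients
#'   a1, b1, a2, b2 and the recorded support overlap of U1 and U2
#' @export
setClass("SyntheticPair", representation(
  I1 = "matrix", I2 = "matrix", shared = "matrix",
  unique1 = "matrix", unique2 = "matrix", color2 = "ArrayOrNULL",
  seed = "numeric", params = "list"
))

setValidity("SyntheticPair", function(object) {
  msg <- character()
  rng <- range(object@I1, object@I2)
  if (rng[1] < 0 || rng[2] > 1) msg <- c(msg, "I1/I2 must lie in [0,1]")
  if (!identical(dim(object@I1), dim(object@I2)))
    msg <- c(msg, "I1 and I2 must share one shape")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticPair modality-1 image
#' @param x a \code{SyntheticPair}
#' @export
modality1 <- function(x) x@I1

#' @describeIn SyntheticPair modality-2 image
#' @export
modality2 <- function(x) x@I2

#' @describeIn SyntheticPair ground-truth decomposition as a named list
#' @export
groundTruth <- function(x) {
  list(shared = x@shared, unique1 = x@unique1, unique2 = x@unique2)
}

setMethod("show", "SyntheticPair", function(object) {
  d <- dim(object@I1)
  cat(sprintf(
    "SyntheticPair %dx%d (seed %d)%s, support overlap %.3f\n",
    d[1], d[2], object@seed,
    if (!is.null(object@color2)) " + RGB companion" else "",
    if (is.null(object@params$overlap)) NA_real_ else object@params$overlap))
})

#' Fusion-quality metric report
#'
#' @slot values named numeric metric values (keys SD, SF, QMI, QNCIE, QG,
#'   MSSSIM, SCD); metrics defined only in third-party specifications
#'   (QM, QS, QCB, VIFF) are intentionally absent
#' @slot params parameter record (histogram bins, window sizes, constants)
#' @slot images identifiers of the evaluated images
#' @export
setClass("MetricReport", representation(
  values = "numeric", params = "list", images = "character"
))

setValidity("MetricReport", function(object) {
  if (any(!is.finite(object@values)))
    return(paste("non-finite metric:",
                 paste(names(object@values)[!is.finite(object@values)],
                       collapse = ", ")))
  TRUE
})

#' @describeIn MetricReport metric values as a named numeric vector
#' @param x a \code{MetricReport}
#' @export
metricValues <- function(x) x@values

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport:", paste(sprintf("%s=%.4f", names(object@values),
                                     object@values), collapse = " "), "\n")
})
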