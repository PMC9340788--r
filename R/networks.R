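# Encoder/decoder construction and the forward/backward machinery.
# A network is a list of three "layers"; each layer is
#   list(W = (9*Cin) x Cout kernel matrix, b = Cout bias,
#        bn = NULL | list(gamma, beta, rm, rv), act = "relu" | "sigmoid")
# The kernel matrix rows follow the array layout dim = c(3, 3, Cin):
# row = di + 3*dj + 9*c with di/dj the vertical/horizontal offsets.
# Images and feature batches are H x W x C x N arrays; single feature maps
# are H x W x V arrays.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

kaiming_kernel <- function(cin, cout) {
  bound <- sqrt(6 / (9 * cin))
  matrix(runif(9 * cin * cout, -bound, bound), 9 * cin, cout)
}

new_layer <- function(cin, cout, bn, act) {
  l <- list(W = kaiming_kernel(cin, cout), b = numeric(cout), bn = NULL,
            act = act)
  if (bn) l$bn <- list(gamma = rep(1, cout), beta = numeric(cout),
                       rm = numeric(cout), rv = rep(1, cout))
  l
}

#' Build one encoder branch
#'
#' Three 3x3 stride-1 convolution blocks with ReLU activations and batch
#' normalization after the second and third block only; channel path
#' \code{inChannels -> baseChannels -> baseChannels -> outChannels}.
#' Kernels are Kaiming-uniform initialized, biases zero (seed the R RNG
#' beforehand for reproducibility).
#'
#' @param config a \code{\link{netConfig}}
#' @return an encoder (list of three layers) usable with
#'   \code{\link{encodePair}}
#' @export
buildEncoder <- function(config) {
  validObject(config)
  list(new_layer(config@inChannels, config@baseChannels, FALSE, "relu"),
       new_layer(config@baseChannels, config@baseChannels, TRUE, "relu"),
       new_layer(config@baseChannels, config@outChannels, TRUE, "relu"))
}

#' Build the shared decoder
#'
#' Symmetric to the encoder: \code{outChannels -> baseChannels ->
#' baseChannels -> inChannels} with ReLU + batch norm on the first two
#' blocks and a sigmoid output (no normalization), so decoded images always
#' lie in [0,1].
#'
#' @param config a \code{\link{netConfig}}
#' @return a decoder (list of three layers)
#' @export
buildDecoder <- function(config) {
  validObject(config)
  list(new_layer(config@outChannels, config@baseChannels, TRUE, "relu"),
       new_layer(config@baseChannels, config@baseChannels, TRUE, "relu"),
       new_layer(config@baseChannels, config@inChannels, FALSE, "sigmoid"))
}

#' Create an untrained three-branch fusion model
#'
#' @param config a \code{\link{netConfig}}
#' @param seed optional integer seed for the parameter initialization
#' @return a \code{\linkS4class{FusionModel}} with independently
#'   initialized En_C1, En_C2, the single shared En_R and the single
#'   shared De_S
#' @export
newFusionModel <- function(config = netConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new("FusionModel",
      encC1 = buildEncoder(config), encC2 = buildEncoder(config),
      encR = buildEncoder(config), dec = buildDecoder(config),
      config = config, trained = FALSE, iterations = 0)
}

# ---- batched activations ------------------------------------------------
# An activation batch is a plain (H*W*N) x C matrix: N sample blocks of
# H*W rows each, spatial positions flattened column-major. shp = c(H,W,N).

layer_fwd <- function(layer, x, shp, train, keep_cache = train) {
  cf <- cpp_conv3_fwd_batch(x, shp[1], shp[2], shp[3], layer$W, layer$b,
                            keep_cache)
  z <- cf$y
  cache <- if (keep_cache) list(cols = cf$cols) else NULL
  if (!is.null(layer$bn)) {
    if (train) {
      bf <- cpp_bn_fwd_train(z, layer$bn$gamma, layer$bn$beta, BN_EPS)
      layer$bn$rm <- (1 - BN_MOMENTUM) * layer$bn$rm +
        BN_MOMENTUM * as.vector(bf$mu)
      layer$bn$rv <- (1 - BN_MOMENTUM) * layer$bn$rv +
        BN_MOMENTUM * as.vector(bf$va)
      if (keep_cache) {
        cache$xhat <- bf$xhat
        cache$va <- as.vector(bf$va)
      }
      z <- bf$y
    } else {
      z <- cpp_bn_fwd_eval(z, layer$bn$gamma, layer$bn$beta,
                           layer$bn$rm, layer$bn$rv, BN_EPS)
    }
  }
  y <- if (layer$act == "relu") pmax(z, 0) else 1 / (1 + exp(-z))
  if (keep_cache) cache$y <- y
  list(y = y, cache = cache, layer = layer)
}

layer_bwd <- function(layer, cache, gy, shp, need_gx = TRUE) {
  y <- cache$y
  gz <- if (layer$act == "relu") gy * (y > 0) else gy * y * (1 - y)
  grads <- list()
  if (!is.null(layer$bn)) {
    bb <- cpp_bn_bwd(gz, cache$xhat, cache$va, layer$bn$gamma, BN_EPS)
    gz <- bb$gx
    grads$ggamma <- as.vector(bb$ggamma)
    grads$gbeta <- as.vector(bb$gbeta)
  }
  bw <- cpp_conv3_bwd_batch(cache$cols, shp[1], shp[2], shp[3], layer$W,
                            gz, need_gx)
  grads$gW <- bw$gW; grads$gb <- as.vector(bw$gb)
  list(gx = bw$gx, grads = grads)
}

net_fwd <- function(net, x, shp, train = FALSE, keep_cache = train) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    f <- layer_fwd(net[[i]], x, shp, train, keep_cache)
    x <- f$y
    net[[i]] <- f$layer
    if (keep_cache) caches[[i]] <- f$cache
  }
  list(y = x, caches = caches, net = net)
}

net_bwd <- function(net, caches, gy, shp, need_input_grad = TRUE) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    b <- layer_bwd(net[[i]], caches[[i]], gy, shp,
                   need_gx = (i > 1 || need_input_grad))
    gy <- b$gx
    grads[[i]] <- b$grads
  }
  list(gx = gy, grads = grads)
}

as_batch <- function(img) matrix(img, length(img), 1)

check_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(name, " must be a numeric matrix")
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop(name, " values must lie in [0,1]")
  invisible(img)
}

#' Encode an image pair into complementary and redundant features
#'
#' Runs both images through the three encoder branches in evaluation mode:
#' C1 = En_C1(I1), C2 = En_C2(I2), R1 = En_R(I1), R2 = En_R(I2). The
#' redundant features of both images come from the single shared encoder.
#'
#' @param model a \code{\linkS4class{FusionModel}}
#' @param I1,I2 co-registered images, numeric matrices in [0,1] of one shape
#' @return list with H x W x V arrays \code{C1}, \code{C2}, \code{R1},
#'   \code{R2}; all values are >= 0 (final ReLU)
#' @export
encodePair <- function(model, I1, I2) {
  check_image(I1, "I1"); check_image(I2, "I2")
  if (!identical(dim(I1), dim(I2)))
    stop("I1 and I2 must have identical shapes")
  shp <- c(dim(I1), 1)
  sq <- function(y) array(y, c(dim(I1), ncol(y)))
  list(C1 = sq(net_fwd(model@encC1, as_batch(I1), shp)$y),
       C2 = sq(net_fwd(model@encC2, as_batch(I2), shp)$y),
       R1 = sq(net_fwd(model@encR, as_batch(I1), shp)$y),
       R2 = sq(net_fwd(model@encR, as_batch(I2), shp)$y))
}

#' Decode a complementary/redundant feature combination
#'
#' Returns De_S(C + R): the features are added elementwise and decoded by
#' the shared decoder (evaluation mode). With \code{R = 0} this decodes the
#' complementary features alone.
#'
#' @param model a \code{\linkS4class{FusionModel}}
#' @param C,R H x W x V feature arrays of one shape
#' @return the decoded image, a matrix in [0,1] with the features' spatial
#'   shape
#' @export
reconstruct <- function(model, C, R) {
  if (!identical(dim(C), dim(R)))
    stop("C and R must have identical shapes")
  decodeFeatures(model, C + R)
}

#' @describeIn reconstruct decode a single (already combined) feature map
#' @param feat H x W x V feature array
#' @export
decodeFeatures <- function(model, feat) {
  if (length(dim(feat)) != 3 || dim(feat)[3] != model@config@outChannels)
    stop("feature channel count does not match the decoder input (",
         model@config@outChannels, ")")
  d <- dim(feat)
  y <- net_fwd(model@dec, matrix(feat, d[1] * d[2], d[3]),
               c(d[1], d[2], 1))$y
  matrix(y, d[1], d[2])
}

#' Cross-reconstruct: swap the redundant features of the pair
#'
#' I12 = De_S(C1 + R2) should resemble I1 (its complementary source) and
#' I21 = De_S(C2 + R1) should resemble I2; during training this is the
#' signal that the complementary features determine an image's appearance.
#'
#' @param model a \code{\linkS4class{FusionModel}}
#' @param C1,C2,R1,R2 feature arrays of one shape (see
#'   \code{\link{encodePair}})
#' @return list of images \code{I12}, \code{I21}
#' @export
crossReconstruct <- function(model, C1, C2, R1, R2) {
  dims <- list(dim(C1), dim(C2), dim(R1), dim(R2))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all feature maps must share one shape")
  list(I12 = reconstruct(model, C1, R2), I21 = reconstruct(model, C2, R1))
}

#' Initialize the encoders from VGG-19 first-layer kernels
#'
#' Maps the first three VGG-19 convolutions onto the encoder channel path:
#' conv1_1 (3->64) to block 1, conv1_2 (64->64) to block 2 and conv2_1
#' (64->128) to block 3, for all three encoder branches. Because the model
#' takes single-channel input, the conv1_1 kernel is averaged over its
#' three input channels, which preserves the response magnitude for gray
#' inputs. The decoder is untouched. Initialization only: the kernels are
#' fine-tuned during training.
#'
#' @param model a \code{\linkS4class{FusionModel}} whose config has
#'   \code{baseChannels = 64} and \code{outChannels = 128}
#' @param vggWeights a list with arrays \code{conv1_1} (3x3x3x64),
#'   \code{conv1_2} (3x3x64x64), \code{conv2_1} (3x3x64x128) and optional
#'   bias vectors \code{b1_1}, \code{b1_2}, \code{b2_1}; or a path to an
#'   RDS file holding such a list; or NULL
#' @return the model with re-initialized encoders; if the weight source is
#'   NULL, unreadable or malformed the model is returned unchanged with a
#'   warning (never a hard failure), and likewise if
#'   \code{config@useVggInit} is FALSE the call is a no-op
#' @export
initFromVGG <- function(model, vggWeights = NULL) {
  if (!model@config@useVggInit) return(model)
  w <- vggWeights
  if (is.character(w))
    w <- suppressWarnings(tryCatch(readRDS(w), error = function(e) NULL))
  ok <- is.list(w) && all(c("conv1_1", "conv1_2", "conv2_1") %in% names(w)) &&
    identical(dim(w$conv1_1), c(3L, 3L, 3L, 64L)) &&
    identical(dim(w$conv1_2), c(3L, 3L, 64L, 64L)) &&
    identical(dim(w$conv2_1), c(3L, 3L, 64L, 128L)) &&
    model@config@inChannels == 1 && model@config@baseChannels == 64 &&
    model@config@outChannels == 128
  if (!ok) {
    warning("VGG weight source unavailable or incompatible; ",
            "keeping random initialization")
    return(model)
  }
  k1 <- apply(w$conv1_1, c(1, 2, 4), mean)          # 3 x 3 x 64
  kernels <- list(matrix(k1, 9, 64),
                  matrix(w$conv1_2, 9 * 64, 64),
                  matrix(w$conv2_1, 9 * 64, 128))
  biases <- list(w$b1_1, w$b1_2, w$b2_1)
  for (branch in c("encC1", "encC2", "encR")) {
    net <- slot(model, branch)
    for (i in 1:3) {
      net[[i]]$W <- kernels[[i]]
      if (!is.null(biases[[i]])) net[[i]]$b <- as.numeric(biases[[i]])
    }
    slot(model, branch) <- net
  }
  model
}

# ---- flat parameter access for the optimizer ----------------------------

model_nets <- function(model)
  list(encC1 = model@encC1, encC2 = model@encC2, encR = model@encR,
       dec = model@dec)

collect_params <- function(nets) {
  out <- list()
  for (bn in names(nets)) for (i in seq_along(nets[[bn]])) {
    l <- nets[[bn]][[i]]
    out[[paste(bn, i, "W", sep = ".")]] <- l$W
    out[[paste(bn, i, "b", sep = ".")]] <- l$b
    if (!is.null(l$bn)) {
      out[[paste(bn, i, "gamma", sep = ".")]] <- l$bn$gamma
      out[[paste(bn, i, "beta", sep = ".")]] <- l$bn$beta
    }
  }
  out
}

assign_params <- function(nets, params) {
  for (nm in names(params)) {
    p <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(p[2])
    if (p[3] %in% c("W", "b")) nets[[p[1]]][[i]][[p[3]]] <- params[[nm]]
    else nets[[p[1]]][[i]]$bn[[p[3]]] <- params[[nm]]
  }
  nets
}
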