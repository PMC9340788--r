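# Image, configuration, checkpoint and manifest I/O. Internal intensity
# convention is [0,1] everywhere; files are 8- or 16-bit PNG/TIFF.

img_luma <- function(arr) {
  # BT.601 luminance of an H x W x >=3 array (alpha ignored)
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

#' Read an image file
#'
#' Supports 8- and 16-bit PNG and TIFF. Values are scaled to [0,1]; in
#' gray mode RGB inputs are converted by BT.601 luminance and an alpha
#' channel is dropped.
#'
#' @param path a .png, .tif or .tiff file
#' @param mode "gray" (matrix) or "rgb" (H x W x 3 array)
#' @return matrix or array with values in [0,1]
#' @export
readImage <- function(path, mode = c("gray", "rgb")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format '", ext, "': ", path))
  nd <- length(dim(img))
  if (mode == "gray") {
    if (nd == 2) img else img_luma(img)
  } else {
    if (nd == 2) array(rep(img, 3), c(dim(img), 3)) else img[, , 1:3]
  }
}

#' Write an image file
#'
#' Values are quantized to the requested bit depth with round-half-up
#' (0.5 at 8 bit stores 128) and written losslessly. Out-of-range values
#' are clipped with a warning.
#'
#' @param img matrix (gray) or H x W x 3 array (RGB) with values in [0,1]
#' @param path output .png, .tif or .tiff path
#' @param bitDepth 8 or 16 (PNG output is always stored as 8-bit; use
#'   TIFF for 16-bit storage)
#' @return the path, invisibly
#' @export
writeImage <- function(img, path, bitDepth = 8) {
  if (!bitDepth %in% c(8, 16)) stop("bitDepth must be 8 or 16")
  if (min(img) < 0 || max(img) > 1) {
    warning("image values outside [0,1] were clipped")
    img <- pmin(pmax(img, 0), 1)
  }
  scale <- 2^bitDepth - 1
  q <- floor(img * scale + 0.5) / scale
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(q, path, dpi = NULL),
         tif = , tiff = tiff::writeTIFF(q, path,
                                        bits.per.sample = as.integer(bitDepth)),
         stop("unsupported image format '", ext, "': ", path))
  invisible(path)
}

# ---- configuration -------------------------------------------------------

CONFIG_KEYS <- c(
  "lambda_ssim", "lambda_r", "lambda_c", "block_radius",
  "similarity_epsilon", "detach_weights", "flip_sign",
  "lc_normalization",
  "batch_size", "learning_rate", "patch_size", "n_folds", "iterations",
  "seed", "use_lc",
  "in_channels", "base_channels", "out_channels", "use_vgg_init")

#' Load a validated training configuration from YAML
#'
#' Unset keys fall back to the standard defaults (lambda_ssim = 1000,
#' lambda_r = lambda_c = 10, batch_size = 8, learning_rate = 1e-4,
#' patch_size = 120, block_radius = 1, n_folds = 10); an empty file yields
#' the full default bundle. Unknown keys and constraint violations raise
#' validation errors naming the key.
#'
#' @param path a YAML file with flat keys from the documented set, or
#'   NULL for pure defaults
#' @return a \code{\link{trainConfig}} (with embedded loss and net
#'   configs)
#' @export
loadConfig <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    unknown <- setdiff(names(vals), CONFIG_KEYS)
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  num_keys <- c("lambda_ssim", "lambda_r", "lambda_c", "block_radius",
                "similarity_epsilon", "batch_size", "learning_rate",
                "patch_size", "n_folds", "iterations", "seed",
                "in_channels", "base_channels", "out_channels")
  g <- function(key, default) {
    v <- vals[[key]]
    if (is.null(v)) return(default)
    if (key %in% num_keys) {
      # YAML 1.1 reads exponent forms like 1e-3 as strings
      v <- suppressWarnings(as.numeric(v))
      if (is.na(v)) stop("config key '", key, "' is not numeric")
    }
    v
  }
  lc <- tryCatch(
    lossConfig(lambdaSsim = g("lambda_ssim", 1000),
               lambdaR = g("lambda_r", 10), lambdaC = g("lambda_c", 10),
               blockRadius = g("block_radius", 1),
               similarityEpsilon = g("similarity_epsilon", 1e-4),
               detachWeights = g("detach_weights", TRUE),
               flipSign = g("flip_sign", FALSE),
               lcNormalization = g("lc_normalization", "sum")),
    error = function(e) stop("invalid loss config: ", conditionMessage(e)))
  nc <- tryCatch(
    netConfig(inChannels = g("in_channels", 1),
              baseChannels = g("base_channels", 64),
              outChannels = g("out_channels", 128),
              useVggInit = g("use_vgg_init", FALSE)),
    error = function(e) stop("invalid net config: ", conditionMessage(e)))
  tryCatch(
    trainConfig(batchSize = g("batch_size", 8),
                learningRate = g("learning_rate", 1e-4),
                patchSize = g("patch_size", 120),
                nFolds = g("n_folds", 10),
                iterations = g("iterations", 10000),
                seed = g("seed", 1), useLc = g("use_lc", TRUE),
                lossConfig = lc, netConfig = nc),
    error = function(e) stop("invalid train config: ", conditionMessage(e)))
}

#' Save a training configuration as YAML
#'
#' Round-trips with \code{\link{loadConfig}}.
#'
#' @param config a \code{\link{trainConfig}}
#' @param path output YAML path
#' @return the path, invisibly
#' @export
saveConfig <- function(config, path) {
  lc <- config@lossConfig; nc <- config@netConfig
  yaml::write_yaml(list(
    lambda_ssim = lc@lambdaSsim, lambda_r = lc@lambdaR,
    lambda_c = lc@lambdaC, block_radius = lc@blockRadius,
    similarity_epsilon = lc@similarityEpsilon,
    detach_weights = lc@detachWeights, flip_sign = lc@flipSign,
    lc_normalization = lc@lcNormalization,
    batch_size = config@batchSize, learning_rate = config@learningRate,
    patch_size = config@patchSize, n_folds = config@nFolds,
    iterations = config@iterations, seed = config@seed,
    use_lc = config@useLc,
    in_channels = nc@inChannels, base_channels = nc@baseChannels,
    out_channels = nc@outChannels, use_vgg_init = nc@useVggInit), path)
  invisible(path)
}

# ---- checkpoints ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Serializes the parameters to \code{path} and writes a JSON sidecar
#' (\code{path.json}) recording the architecture, training
#' hyper-parameters, seed and package version.
#'
#' @param model a \code{\linkS4class{FusionModel}}
#' @param path checkpoint path (conventionally .rds)
#' @param trainconfig optional \code{\link{trainConfig}} recorded in the
#'   sidecar
#' @return the path, invisibly
#' @export
saveCheckpoint <- function(model, path, trainconfig = NULL) {
  saveRDS(list(encC1 = model@encC1, encC2 = model@encC2,
               encR = model@encR, dec = model@dec,
               trained = model@trained, iterations = model@iterations),
          path)
  nc <- model@config
  side <- list(
    net = list(in_channels = nc@inChannels, base_channels = nc@baseChannels,
               out_channels = nc@outChannels, kernel_size = nc@kernelSize,
               stride = nc@stride, padding = nc@padding,
               use_vgg_init = nc@useVggInit),
    trained = model@trained, iterations = model@iterations,
    package_version = as.character(utils::packageVersion("defusion")))
  if (!is.null(trainconfig))
    side$train <- list(batch_size = trainconfig@batchSize,
                       learning_rate = trainconfig@learningRate,
                       patch_size = trainconfig@patchSize,
                       iterations = trainconfig@iterations,
                       seed = trainconfig@seed, use_lc = trainconfig@useLc)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by \code{\link{saveCheckpoint}}
#'
#' @param path checkpoint path
#' @return a \code{\linkS4class{FusionModel}}
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json")))
    stop("invalid checkpoint: missing ", path, " or its .json sidecar")
  blob <- readRDS(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- netConfig(inChannels = side$net$in_channels,
                   baseChannels = side$net$base_channels,
                   outChannels = side$net$out_channels,
                   useVggInit = isTRUE(side$net$use_vgg_init))
  fix <- function(net) lapply(net, function(l) {
    l$W <- as.matrix(l$W); l
  })
  new("FusionModel", encC1 = fix(blob$encC1), encC2 = fix(blob$encC2),
      encR = fix(blob$encR), dec = fix(blob$dec), config = cfg,
      trained = isTRUE(blob$trained),
      iterations = as.numeric(blob$iterations))
}

# ---- dataset directories -------------------------------------------------

#' Write a dataset of pairs as PNGs plus a JSON manifest
#'
#' Produces \code{pair_0001_m1.png}, \code{pair_0001_m2.png}, optionally
#' \code{pair_0001_m2_rgb.png}, ground-truth images
#' (\code{_shared/_u1/_u2}) for synthetic pairs, and \code{manifest.json}
#' listing every record with the dataset-level seed and generator
#' parameters.
#'
#' @param pairs list of \code{\linkS4class{SyntheticPair}} objects or
#'   lists with \code{I1}, \code{I2}
#' @param dir output directory (created if needed)
#' @param seed dataset-level seed recorded in the manifest
#' @return the manifest path, invisibly
#' @export
writeDataset <- function(pairs, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    id <- sprintf("pair_%04d", i)
    p <- pairs[[i]]
    im <- pair_images(p)
    rec <- list(id = id, m1 = paste0(id, "_m1.png"),
                m2 = paste0(id, "_m2.png"))
    writeImage(im$I1, file.path(dir, rec$m1))
    writeImage(im$I2, file.path(dir, rec$m2))
    if (is(p, "SyntheticPair")) {
      rec$shared <- paste0(id, "_shared.png")
      rec$u1 <- paste0(id, "_u1.png")
      rec$u2 <- paste0(id, "_u2.png")
      writeImage(p@shared, file.path(dir, rec$shared))
      writeImage(p@unique1, file.path(dir, rec$u1))
      writeImage(p@unique2, file.path(dir, rec$u2))
      rec$seed <- p@seed
      if (!is.null(p@color2)) {
        rec$m2_rgb <- paste0(id, "_m2_rgb.png")
        writeImage(p@color2, file.path(dir, rec$m2_rgb))
      }
    }
    records[[i]] <- rec
  }
  manifest <- list(records = records,
                   metadata = list(seed = seed, n = length(pairs),
                                   generator = "defusion synthetic"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' Checks that every referenced file exists and ids are unique.
#'
#' @param dir dataset directory containing \code{manifest.json}
#' @return list with \code{records} and \code{metadata}
#' @export
readManifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- vapply(m$records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate pair ids in manifest")
  for (r in m$records)
    for (key in intersect(names(r), c("m1", "m2", "m2_rgb", "shared",
                                      "u1", "u2")))
      if (!file.exists(file.path(dir, r[[key]])))
        stop("manifest references a missing file: ", r[[key]])
  m
}

#' Load the image pairs of a dataset directory
#'
#' @param dir dataset directory with a manifest
#'   (see \code{\link{writeDataset}})
#' @return list of lists with elements \code{I1}, \code{I2} (and
#'   \code{color2} when an RGB companion exists)
#' @export
loadDataset <- function(dir) {
  m <- readManifest(dir)
  lapply(m$records, function(r) {
    out <- list(I1 = readImage(file.path(dir, r$m1), "gray"),
                I2 = readImage(file.path(dir, r$m2), "gray"))
    if (!is.null(r$m2_rgb))
      out$color2 <- readImage(file.path(dir, r$m2_rgb), "rgb")
    out
  })
}
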