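# Training protocol: paired augmentation, k-fold splitting, the Adam loop
# over the full disentanglement objective, and the k-fold experiment
# driver.

#' Randomly crop and augment a co-registered pair
#'
#' Draws one square crop window and one flip/rotation configuration from
#' the current RNG state and applies them identically to both images, so
#' co-registration is preserved. Rotations are restricted to multiples of
#' 90 degrees (no interpolation artifacts).
#'
#' @param I1,I2 images, matrices of one shape, at least patchSize in both
#'   dimensions
#' @param patchSize side length of the square patch (default 120)
#' @return list with the two augmented patches \code{I1}, \code{I2}
#' @export
augmentPatch <- function(I1, I2, patchSize = 120) {
  check_same_shape(I1, I2, "images")
  H <- nrow(I1); W <- ncol(I1)
  if (H < patchSize || W < patchSize)
    stop("images (", H, "x", W, ") are smaller than the patch size ",
         patchSize)
  r0 <- sample.int(H - patchSize + 1, 1) - 1
  c0 <- sample.int(W - patchSize + 1, 1) - 1
  fh <- runif(1) < 0.5; fv <- runif(1) < 0.5
  k <- sample.int(4, 1) - 1
  tf <- function(x) {
    x <- x[r0 + seq_len(patchSize), c0 + seq_len(patchSize)]
    if (fh) x <- x[, rev(seq_len(ncol(x)))]
    if (fv) x <- x[rev(seq_len(nrow(x))), ]
    for (i in seq_len(k)) x <- t(x[rev(seq_len(nrow(x))), ])  # rotate 90
    x
  }
  list(I1 = tf(I1), I2 = tf(I2))
}

#' k-fold split of item indices
#'
#' Shuffles 1..nItems with the seed and partitions them into nFolds
#' disjoint test sets covering every item exactly once, sizes differing by
#' at most one.
#'
#' @param nItems number of items (>= nFolds)
#' @param nFolds number of folds (>= 2)
#' @param seed RNG seed for the shuffle
#' @return list of length nFolds, each a list with integer vectors
#'   \code{train} and \code{test}
#' @export
kfoldSplit <- function(nItems, nFolds, seed = 1) {
  if (nFolds < 2) stop("nFolds must be >= 2")
  if (nItems < nFolds) stop("nItems must be >= nFolds")
  perm <- with_seed(seed, sample.int(nItems))
  fold_of <- rep(seq_len(nFolds), length.out = nItems)
  lapply(seq_len(nFolds), function(f) {
    test <- sort(perm[fold_of == f])
    list(train = setdiff(seq_len(nItems), test), test = test)
  })
}

# ---- one gradient step ---------------------------------------------------

zero_like <- function(params) lapply(params, function(p) p * 0)

acc_grads <- function(acc, branch, grads) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    acc[[paste(branch, i, "W", sep = ".")]] <-
      acc[[paste(branch, i, "W", sep = ".")]] + g$gW
    acc[[paste(branch, i, "b", sep = ".")]] <-
      acc[[paste(branch, i, "b", sep = ".")]] + g$gb
    if (!is.null(g$ggamma)) {
      acc[[paste(branch, i, "gamma", sep = ".")]] <-
        acc[[paste(branch, i, "gamma", sep = ".")]] + g$ggamma
      acc[[paste(branch, i, "beta", sep = ".")]] <-
        acc[[paste(branch, i, "beta", sep = ".")]] + g$gbeta
    }
  }
  acc
}

# Full forward + backward over one batch. X1, X2: (H*W*N) x 1 activation
# matrices, shp = c(H, W, N). Returns the loss breakdown, the parameter
# gradients and the nets with updated batch-norm running statistics.
training_step <- function(nets, X1, X2, shp, lcfg, useLc = TRUE,
                          want_grads = TRUE) {
  H <- shp[1]; W <- shp[2]; N <- shp[3]; P <- H * W
  rows_of <- function(n) (n - 1) * P + seq_len(P)
  fC1 <- net_fwd(nets$encC1, X1, shp, train = TRUE); nets$encC1 <- fC1$net
  fC2 <- net_fwd(nets$encC2, X2, shp, train = TRUE); nets$encC2 <- fC2$net
  fR1 <- net_fwd(nets$encR, X1, shp, train = TRUE);  nets$encR <- fR1$net
  fR2 <- net_fwd(nets$encR, X2, shp, train = TRUE);  nets$encR <- fR2$net
  C1 <- fC1$y; C2 <- fC2$y; R1 <- fR1$y; R2 <- fR2$y

  dec_pass <- function(feat) {
    f <- net_fwd(nets$dec, feat, shp, train = TRUE)
    nets$dec <<- f$net
    f
  }
  d11 <- dec_pass(C1 + R1); d22 <- dec_pass(C2 + R2)
  d12 <- dec_pass(C1 + R2); d21 <- dec_pass(C2 + R1)
  dr1 <- dec_pass(R1);      dr2 <- dec_pass(R2)

  outs <- list(d11$y, d12$y, d22$y, d21$y)
  tgts <- list(X1, X1, X2, X2)
  gouts <- vector("list", 4)
  lmse <- 0; lssim <- 0
  for (i in 1:4) {
    diff <- outs[[i]] - tgts[[i]]
    lmse <- lmse + mean(diff^2)
    g <- 2 * diff / length(diff)
    for (n in seq_len(N)) {
      rw <- rows_of(n)
      sg <- ssim_with_grad(matrix(outs[[i]][rw, 1], H, W),
                           matrix(tgts[[i]][rw, 1], H, W))
      lssim <- lssim + (1 - sg$value) / N
      # d/dx of lambdaSsim * (1 - ssim) averaged over the batch
      g[rw, 1] <- g[rw, 1] - lcfg@lambdaSsim * as.vector(sg$grad) / N
    }
    gouts[[i]] <- g
  }

  ldiff <- dr1$y - dr2$y
  lr <- mean(abs(ldiff))
  glr <- sign(ldiff) / length(ldiff)

  lc <- 0
  gLc1 <- matrix(0, nrow(C1), ncol(C1)); gLc2 <- gLc1
  dn <- c(H, W, ncol(C1))
  for (n in seq_len(N)) {
    rw <- rows_of(n)
    res <- lc_internal(array(C1[rw, ], dn), array(C2[rw, ], dn),
                       lcfg, with_grad = want_grads && useLc &&
                         lcfg@lambdaC > 0)
    if (is.list(res)) {
      lc <- lc + res$value / N
      gLc1[rw, ] <- matrix(res$g1, P, dn[3]) / N
      gLc2[rw, ] <- matrix(res$g2, P, dn[3]) / N
    } else lc <- lc + res / N
  }

  loss <- totalLoss(lmse, lssim, lr, if (useLc) lc else 0, lcfg)
  breakdown <- new("LossBreakdown", lMse = lmse, lSsim = lssim,
                   lRec = loss@lRec, lR = lr, lC = lc,
                   total = loss@lRec + lcfg@lambdaR * lr +
                     (if (useLc) lcfg@lambdaC * lc else 0))
  if (!want_grads)
    return(list(loss = breakdown, nets = nets, grads = NULL))

  acc <- zero_like(collect_params(nets))
  bwd_dec <- function(pass, gy) {
    b <- net_bwd(nets$dec, pass$caches, gy, shp)
    acc <<- acc_grads(acc, "dec", b$grads)
    b$gx
  }
  g11 <- bwd_dec(d11, gouts[[1]])
  g12 <- bwd_dec(d12, gouts[[2]])
  g22 <- bwd_dec(d22, gouts[[3]])
  g21 <- bwd_dec(d21, gouts[[4]])
  gr1 <- bwd_dec(dr1, lcfg@lambdaR * glr)
  gr2 <- bwd_dec(dr2, -lcfg@lambdaR * glr)

  gC1 <- g11 + g12
  gC2 <- g22 + g21
  gR1 <- g11 + g21 + gr1
  gR2 <- g22 + g12 + gr2
  if (useLc && lcfg@lambdaC > 0) {
    gC1 <- gC1 + lcfg@lambdaC * gLc1
    gC2 <- gC2 + lcfg@lambdaC * gLc2
  }
  bC1 <- net_bwd(nets$encC1, fC1$caches, gC1, shp, FALSE)
  acc <- acc_grads(acc, "encC1", bC1$grads)
  bC2 <- net_bwd(nets$encC2, fC2$caches, gC2, shp, FALSE)
  acc <- acc_grads(acc, "encC2", bC2$grads)
  bR1 <- net_bwd(nets$encR, fR1$caches, gR1, shp, FALSE)
  acc <- acc_grads(acc, "encR", bR1$grads)
  bR2 <- net_bwd(nets$encR, fR2$caches, gR2, shp, FALSE)
  acc <- acc_grads(acc, "encR", bR2$grads)

  list(loss = breakdown, nets = nets, grads = acc)
}

pair_images <- function(item) {
  if (is(item, "SyntheticPair")) list(I1 = item@I1, I2 = item@I2)
  else if (is.list(item) && all(c("I1", "I2") %in% names(item)))
    list(I1 = item$I1, I2 = item$I2)
  else stop("dataset items must be SyntheticPair objects or ",
            "lists with elements I1 and I2")
}

#' Train the three-branch fusion auto-encoder
#'
#' Minimizes \code{lRec + lambdaR lR + lambdaC lC} by Adam (default
#' moments 0.9/0.999): every iteration samples \code{batchSize} pairs with
#' replacement, crops and augments each (\code{\link{augmentPatch}};
#' images exactly the patch size are only flipped/rotated), runs the three
#' encoders and the six decoder passes, and backpropagates the full
#' objective. With \code{config@useLc = FALSE} the group-lasso term is
#' dropped from the objective (ablated model) but still logged; the same
#' happens when \code{lambdaC = 0}, and \code{lambdaR = 0} likewise
#' reduces training to plain (cross-)reconstruction.
#'
#' @param model a \code{\linkS4class{FusionModel}}
#' @param dataset list of \code{\linkS4class{SyntheticPair}} objects or of
#'   lists with elements \code{I1}, \code{I2}
#' @param config a \code{\link{trainConfig}}
#' @param logEvery record the loss breakdown every this many iterations
#'   (default 1); a JSONL log is written to \code{logFile} if given
#' @param logFile optional path for a machine-readable JSONL loss log
#' @return list with the trained \code{model} and \code{record}, a
#'   data.frame with one row per logged iteration (iteration, lMse, lSsim,
#'   lRec, lR, lC, total)
#' @export
trainFusionModel <- function(model, dataset, config = trainConfig(),
                             logEvery = 1, logFile = NULL) {
  validObject(config)
  if (length(dataset) == 0) stop("dataset is empty")
  set.seed(config@seed)
  nets <- model_nets(model)
  params <- collect_params(nets)
  m <- zero_like(params); v <- zero_like(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lcfg <- config@lossConfig
  ps <- config@patchSize
  hist <- vector("list", config@iterations)
  con <- if (!is.null(logFile)) file(logFile, "w") else NULL
  on.exit(if (!is.null(con)) close(con))

  P <- ps * ps
  for (it in seq_len(config@iterations)) {
    idx <- sample.int(length(dataset), config@batchSize, replace = TRUE)
    X1 <- matrix(0, P * config@batchSize, 1)
    X2 <- matrix(0, P * config@batchSize, 1)
    for (j in seq_along(idx)) {
      im <- pair_images(dataset[[idx[j]]])
      patch <- augmentPatch(im$I1, im$I2, ps)
      X1[(j - 1) * P + seq_len(P), 1] <- patch$I1
      X2[(j - 1) * P + seq_len(P), 1] <- patch$I2
    }
    step <- training_step(nets, X1, X2, c(ps, ps, config@batchSize),
                          lcfg, config@useLc)
    nets <- step$nets
    if (!is.finite(step$loss@total))
      stop("non-finite loss at iteration ", it, ": ",
           paste(sprintf("%s=%g", names(lossComponents(step$loss)),
                         lossComponents(step$loss)), collapse = " "))
    params <- collect_params(nets)
    for (nm in names(params)) {
      g <- step$grads[[nm]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g * g
      mhat <- m[[nm]] / (1 - b1^it)
      vhat <- v[[nm]] / (1 - b2^it)
      params[[nm]] <- params[[nm]] -
        config@learningRate * mhat / (sqrt(vhat) + eps)
    }
    nets <- assign_params(nets, params)
    if (it %% logEvery == 0 || it == config@iterations) {
      comp <- lossComponents(step$loss)
      hist[[it]] <- c(iteration = it, comp)
      if (!is.null(con))
        writeLines(jsonlite::toJSON(as.list(c(iteration = it, comp)),
                                    auto_unbox = TRUE, digits = NA), con)
    }
  }
  record <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null,
                                                      logical(1))]))
  model@encC1 <- nets$encC1; model@encC2 <- nets$encC2
  model@encR <- nets$encR; model@dec <- nets$dec
  model@trained <- TRUE
  model@iterations <- model@iterations + config@iterations
  list(model = model, record = record)
}

#' Calibrate batch-normalization running statistics
#'
#' Runs forward passes of the full training graph (encoders and all six
#' decoder passes) in training mode over batches drawn from the dataset,
#' updating only the batch-norm running means/variances; no parameter is
#' modified. A freshly initialized model has running statistics (mean 0,
#' variance 1) that no data ever produced, so its evaluation-mode outputs
#' are degenerate; calibration makes an untrained model a meaningful
#' reference for before/after comparisons.
#'
#' @param model a \code{\linkS4class{FusionModel}}
#' @param dataset list of pairs (as in \code{\link{trainFusionModel}})
#' @param passes number of forward batches (default 10)
#' @param batchSize pairs per batch (default 2)
#' @param seed RNG seed for batch sampling
#' @return the model with updated running statistics
#' @export
calibrateBatchNorm <- function(model, dataset, passes = 10, batchSize = 2,
                               seed = 1) {
  set.seed(seed)
  nets <- model_nets(model)
  im0 <- pair_images(dataset[[1]])
  P <- length(im0$I1)
  shp <- c(dim(im0$I1), batchSize)
  for (it in seq_len(passes)) {
    idx <- sample.int(length(dataset), batchSize, replace = TRUE)
    X1 <- matrix(0, P * batchSize, 1)
    X2 <- matrix(0, P * batchSize, 1)
    for (j in seq_along(idx)) {
      im <- pair_images(dataset[[idx[j]]])
      X1[(j - 1) * P + seq_len(P), 1] <- im$I1
      X2[(j - 1) * P + seq_len(P), 1] <- im$I2
    }
    st <- training_step(nets, X1, X2, shp, lossConfig(), TRUE,
                        want_grads = FALSE)
    nets <- st$nets
  }
  model@encC1 <- nets$encC1; model@encC2 <- nets$encC2
  model@encR <- nets$encR; model@dec <- nets$dec
  model
}

#' Disentanglement recovery / penalty ablation experiment
#'
#' Desk-scale version of the group-lasso ablation: two models with an
#' identical initialization and data stream are trained at matched
#' iterations, one with the complementary group-lasso penalty and one
#' without it, on synthetic pairs with known shared structure. On
#' held-out pairs it measures (a) the redundant consistency
#' mean |De_S(R1) - De_S(R2)| before and after training and (b) the mean
#' per-position cosine similarity between the two complementary feature
#' maps under both models, plus (c) the cross-reconstruction fidelity
#' SSIM(I1, De_S(C1 + R2)) against the inter-modality baseline
#' SSIM(I1, I2).
#'
#' @param seed master seed for data generation, initialization and
#'   training
#' @param nTrain,nTest training and held-out pair counts
#' @param size image size c(H, W)
#' @param iterations training iterations for each of the two runs
#' @param batchSize pairs per gradient step
#' @param learningRate Adam step size
#' @param channels encoder base/output channels of the desk-scale nets
#' @return list with \code{lrUntrained}, \code{lrTrained},
#'   \code{lrRatio}, \code{cosineWithLc}, \code{cosineWithoutLc},
#'   \code{ssimCross}, \code{ssimBaseline} and the two trained models
#'   (\code{modelLc}, \code{modelNoLc}). The untrained reference is the
#'   same initialization with batch-norm statistics calibrated by forward
#'   passes (\code{\link{calibrateBatchNorm}}); without calibration an
#'   untrained model decodes everything to a near-constant image and the
#'   before/after comparison would be vacuous
#' @export
disentanglementExperiment <- function(seed = 1, nTrain = 8, nTest = 4,
                                      size = c(64, 64), iterations = 2000,
                                      batchSize = 2, learningRate = 1e-3,
                                      channels = 8) {
  pairs <- makeDataset(nTrain + nTest, seed = seed, size = size)
  train <- pairs[seq_len(nTrain)]
  test <- pairs[nTrain + seq_len(nTest)]
  nc <- netConfig(1, channels, channels)
  cfg <- trainConfig(batchSize = batchSize, learningRate = learningRate,
                     patchSize = size[1], iterations = iterations,
                     seed = seed, netConfig = nc)
  model0 <- newFusionModel(nc, seed = seed)

  held_out <- function(model) {
    lr <- 0; cs <- 0; sx <- 0; sb <- 0
    for (p in test) {
      f <- encodePair(model, p@I1, p@I2)
      lr <- lr + redundantConsistency(model, f$R1, f$R2) / length(test)
      cs <- cs + mean(cosineSimilarityMap(f$C1, f$C2)) / length(test)
      I12 <- reconstruct(model, f$C1, f$R2)
      sx <- sx + ssimIndex(p@I1, I12) / length(test)
      sb <- sb + ssimIndex(p@I1, p@I2) / length(test)
    }
    list(lr = lr, cos = cs, ssimCross = sx, ssimBaseline = sb)
  }

  base <- held_out(calibrateBatchNorm(model0, train, seed = seed))
  cfgLc <- cfg
  fitLc <- trainFusionModel(model0, train, cfgLc)
  cfgNo <- cfg; cfgNo@useLc <- FALSE
  fitNo <- trainFusionModel(model0, train, cfgNo)
  mLc <- held_out(fitLc$model)
  mNo <- held_out(fitNo$model)

  list(lrUntrained = base$lr, lrTrained = mLc$lr,
       lrRatio = mLc$lr / base$lr,
       cosineWithLc = mLc$cos, cosineWithoutLc = mNo$cos,
       ssimCross = mLc$ssimCross, ssimBaseline = mLc$ssimBaseline,
       modelLc = fitLc$model, modelNoLc = fitNo$model,
       recordLc = fitLc$record, recordNoLc = fitNo$record)
}

#' k-fold verification experiment
#'
#' For each fold: trains a freshly initialized model on the training
#' pairs, fuses every held-out test pair with each requested strategy and
#' evaluates the implemented quality metrics. The summary aggregates the
#' per-fold means with their across-fold mean and variance.
#'
#' @param dataset list of pairs (as in \code{\link{trainFusionModel}}),
#'   at least \code{config@nFolds} long
#' @param config a \code{\link{trainConfig}}
#' @param strategies complementary fusion strategies to evaluate
#' @return list with \code{perFold} (one data.frame of metric values per
#'   fold) and \code{summary} (data.frame with strategy, metric, mean,
#'   variance across folds)
#' @export
runFoldExperiment <- function(dataset, config = trainConfig(),
                              strategies = c("add", "max", "l1")) {
  folds <- kfoldSplit(length(dataset), config@nFolds, config@seed)
  perFold <- list()
  for (f in seq_along(folds)) {
    cfg <- config
    cfg@seed <- config@seed + f
    model <- newFusionModel(config@netConfig, seed = cfg@seed)
    model <- trainFusionModel(model, dataset[folds[[f]]$train], cfg)$model
    rows <- list()
    for (strat in strategies) {
      vals <- sapply(folds[[f]]$test, function(i) {
        im <- pair_images(dataset[[i]])
        fused <- fuseImages(model, im$I1, im$I2, strat)
        metricValues(evaluatePair(im$I1, im$I2, fused))
      })
      rows[[strat]] <- data.frame(fold = f, strategy = strat,
                                  metric = rownames(vals),
                                  value = rowMeans(vals))
    }
    perFold[[f]] <- do.call(rbind, rows)
  }
  all <- do.call(rbind, perFold)
  agg_m <- aggregate(value ~ strategy + metric, all, mean)
  agg_v <- aggregate(value ~ strategy + metric, all, function(x)
    if (length(x) > 1) var(x) else 0)
  summary <- data.frame(strategy = agg_m$strategy, metric = agg_m$metric,
                        mean = agg_m$value, variance = agg_v$value)
  list(perFold = perFold, summary = summary)
}
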