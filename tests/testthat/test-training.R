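test_that("augmentPatch preserves co-registration and patch size", {
  I1 <- rand_img(1, 40, 40)
  I2 <- 1 - I1                      # perfectly co-registered complement
  set.seed(2)
  p <- augmentPatch(I1, I2, 16)
  expect_equal(dim(p$I1), c(16, 16))
  expect_equal(p$I2, 1 - p$I1)      # the same transform hit both images
  expect_error(augmentPatch(I1, I2, 64), "smaller than the patch")
  # determinism under a fixed RNG state
  set.seed(3); a <- augmentPatch(I1, I2, 16)
  set.seed(3); b <- augmentPatch(I1, I2, 16)
  expect_identical(a, b)
  # a horizontal flip applied twice is the identity
  x <- rand_img(4, 8, 8)
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_identical(flip(flip(x)), x)
})

test_that("kfoldSplit partitions items into near-equal disjoint folds", {
  folds <- kfoldSplit(180, 10, seed = 1)
  expect_length(folds, 10)
  sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_true(all(sizes == 18))
  tests <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(tests, 1:180)                 # disjoint cover
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:180)
  }
  # uneven case: sizes differ by at most one
  sizes2 <- vapply(kfoldSplit(23, 5, seed = 2),
                   function(f) length(f$test), integer(1))
  expect_lte(diff(range(sizes2)), 1)
  expect_identical(kfoldSplit(20, 4, seed = 9), kfoldSplit(20, 4, seed = 9))
  expect_error(kfoldSplit(5, 10), ">= nFolds")
  expect_error(kfoldSplit(5, 1), ">= 2")
})

test_that("training step gradients match finite differences end to end", {
  m <- newFusionModel(netConfig(1, 3, 2), seed = 4)
  nets <- defusion:::model_nets(m)
  H <- 12; N <- 2; P <- H * H
  set.seed(5)
  X1 <- matrix(runif(P * N), P * N, 1)
  X2 <- matrix(runif(P * N), P * N, 1)
  shp <- c(H, H, N)
  lcfg <- lossConfig(lambdaSsim = 3, lambdaR = 2, lambdaC = 0.5,
                     detachWeights = FALSE)
  st <- defusion:::training_step(nets, X1, X2, shp, lcfg, TRUE)
  params <- defusion:::collect_params(nets)
  loss_at <- function(params) {
    n2 <- defusion:::assign_params(nets, params)
    defusion:::training_step(n2, X1, X2, shp, lcfg, TRUE,
                             want_grads = FALSE)$loss@total
  }
  eps <- 1e-6
  set.seed(6)
  for (nm in sample(names(params), 8)) {
    i <- sample(length(params[[nm]]), 1)
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(st$grads[[nm]][i], num, tolerance = 5e-3)
  }
})

test_that("training is deterministic and logs the loss breakdown", {
  pairs <- makeDataset(3, seed = 10, size = c(32, 32))
  cfg <- trainConfig(batchSize = 2, learningRate = 1e-3, patchSize = 32,
                     iterations = 8, seed = 11,
                     netConfig = netConfig(1, 4, 4))
  m <- newFusionModel(cfg@netConfig, seed = 11)
  r1 <- trainFusionModel(m, pairs, cfg)
  r2 <- trainFusionModel(m, pairs, cfg)
  expect_identical(r1$record, r2$record)
  expect_equal(nrow(r1$record), 8)
  expect_named(r1$record, c("iteration", "lMse", "lSsim", "lRec", "lR",
                            "lC", "total"))
  expect_true(all(r1$record$total >= 0))
  expect_true(r1$model@trained)
  expect_equal(r1$model@iterations, 8)
  expect_error(trainFusionModel(m, list(), cfg), "empty")
})

test_that("degenerate weights reduce training to plain reconstruction", {
  pairs <- makeDataset(2, seed = 12, size = c(32, 32))
  cfg <- trainConfig(batchSize = 2, learningRate = 1e-3, patchSize = 32,
                     iterations = 4, seed = 13,
                     netConfig = netConfig(1, 4, 4),
                     lossConfig = lossConfig(lambdaR = 0, lambdaC = 0))
  m <- newFusionModel(cfg@netConfig, seed = 13)
  r <- trainFusionModel(m, pairs, cfg)
  # lR and lC are still computed and logged even though unweighted
  expect_true(all(r$record$lR > 0))
  expect_true(all(r$record$lC > 0))
  expect_equal(r$record$total, r$record$lRec, tolerance = 1e-12)
})

test_that("the JSONL loss log mirrors the returned record", {
  pairs <- makeDataset(2, seed = 14, size = c(32, 32))
  cfg <- trainConfig(batchSize = 1, learningRate = 1e-3, patchSize = 32,
                     iterations = 3, seed = 15,
                     netConfig = netConfig(1, 4, 4))
  m <- newFusionModel(cfg@netConfig, seed = 15)
  log <- file.path(tempdir(), "loss.jsonl")
  r <- trainFusionModel(m, pairs, cfg, logFile = log)
  lines <- readLines(log)
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$total, r$record$total[2])
})

test_that("fold experiments aggregate metrics across folds", {
  pairs <- makeDataset(6, seed = 16, size = c(32, 32))
  cfg <- trainConfig(batchSize = 2, learningRate = 1e-3, patchSize = 32,
                     nFolds = 2, iterations = 10, seed = 17,
                     netConfig = netConfig(1, 4, 4))
  res <- runFoldExperiment(pairs, cfg, strategies = c("add", "max"))
  expect_length(res$perFold, 2)
  expect_equal(nrow(res$summary), 7 * 2)     # metrics x strategies
  all_rows <- do.call(rbind, res$perFold)
  for (i in seq_len(nrow(res$summary))) {
    sel <- all_rows$strategy == res$summary$strategy[i] &
      all_rows$metric == res$summary$metric[i]
    expect_equal(res$summary$mean[i], mean(all_rows$value[sel]))
    expect_equal(res$summary$variance[i], var(all_rows$value[sel]))
  }
})
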