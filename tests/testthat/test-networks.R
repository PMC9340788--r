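test_that("encoder and decoder preserve spatial shape across sizes", {
  cfg <- netConfig(1, 4, 6)
  set.seed(1)
  enc <- buildEncoder(cfg)
  dec <- buildDecoder(cfg)
  for (H in c(5, 12, 33)) {
    x <- matrix(runif(H * H), H, H)
    y <- defusion:::net_fwd(enc, defusion:::as_batch(x), c(H, H, 1))$y
    expect_equal(dim(y), c(H * H, 6))
    z <- defusion:::net_fwd(dec, y, c(H, H, 1))$y
    expect_equal(dim(z), c(H * H, 1))
  }
})

test_that("encoder channel path follows the config and output is non-negative", {
  cfg <- netConfig(1, 8, 8)
  set.seed(2)
  enc <- buildEncoder(cfg)
  expect_equal(ncol(enc[[1]]$W), 8)
  expect_equal(nrow(enc[[1]]$W), 9)        # 1 input channel x 3 x 3
  expect_equal(nrow(enc[[3]]$W), 9 * 8)
  expect_null(enc[[1]]$bn)                 # no normalization on block 1
  expect_false(is.null(enc[[2]]$bn))
  expect_false(is.null(enc[[3]]$bn))
  x <- matrix(runif(49), 7, 7)
  y <- defusion:::net_fwd(enc, defusion:::as_batch(x), c(7, 7, 1))$y
  expect_gte(min(y), 0)
})

test_that("decoder output lies in [0,1] for arbitrary inputs and mirrors the path", {
  cfg <- netConfig(1, 4, 6)
  set.seed(3)
  dec <- buildDecoder(cfg)
  expect_null(dec[[3]]$bn)                 # sigmoid block is unnormalized
  expect_identical(dec[[3]]$act, "sigmoid")
  x <- matrix(rnorm(36 * 6, sd = 10), 36, 6)
  y <- defusion:::net_fwd(dec, x, c(6, 6, 1))$y
  expect_gte(min(y), 0)
  expect_lte(max(y), 1)
  # all-zero input with zero-initialized final bias decodes to 0.5
  dec0 <- lapply(dec, function(l) { l$W[] <- 0; l$b[] <- 0; l })
  y0 <- defusion:::net_fwd(dec0, matrix(0, 36, 6), c(6, 6, 1))$y
  expect_equal(as.vector(y0), rep(0.5, 36))
})

test_that("invalid configurations are rejected", {
  expect_error(netConfig(0, 4, 4), "positive integer")
  expect_error(netConfig(1, -2, 4), "positive integer")
  expect_error(netConfig(1, 4.5, 4), "positive integer")
})

test_that("encodePair uses the shared redundant encoder deterministically", {
  m <- tiny_model(seed = 5)
  img <- rand_img(6, 12, 12)
  f <- encodePair(m, img, img)
  expect_identical(f$R1, f$R2)             # same encoder, same input
  expect_false(isTRUE(all.equal(f$C1, f$C2)))  # distinct parameter sets
  expect_equal(dim(f$C1), c(12, 12, 4))
  expect_gte(min(f$C1, f$C2, f$R1, f$R2), 0)
  expect_error(encodePair(m, img, rand_img(7, 10, 10)), "identical shapes")
  expect_error(encodePair(m, img * 2, img), "\\[0,1\\]")
})

test_that("reconstruct adds features commutatively and honors shape", {
  m <- tiny_model(seed = 8)
  img <- rand_img(9, 14, 14)
  f <- encodePair(m, img, img)
  zero <- f$R1 * 0
  expect_equal(reconstruct(m, f$C1, zero), decodeFeatures(m, f$C1))
  expect_equal(reconstruct(m, f$C1, f$R1), reconstruct(m, f$R1, f$C1))
  out <- reconstruct(m, f$C1, f$R1)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(reconstruct(m, f$C1, f$R1[1:10, , ]), "identical shapes")
})

test_that("cross reconstruction swaps redundant features", {
  m <- tiny_model(seed = 10)
  I1 <- rand_img(11, 12, 12); I2 <- rand_img(12, 12, 12)
  f <- encodePair(m, I1, I2)
  x <- crossReconstruct(m, f$C1, f$C2, f$R1, f$R2)
  expect_equal(x$I12, reconstruct(m, f$C1, f$R2))
  expect_equal(x$I21, reconstruct(m, f$C2, f$R1))
  # R1 = R2 makes the cross reconstruction equal the self reconstruction
  x2 <- crossReconstruct(m, f$C1, f$C2, f$R1, f$R1)
  expect_identical(x2$I12, reconstruct(m, f$C1, f$R1))
  expect_true(all(x$I12 >= 0 & x$I12 <= 1 & x$I21 >= 0 & x$I21 <= 1))
})

test_that("fixed seeds reproduce initialization exactly", {
  m1 <- newFusionModel(netConfig(1, 4, 4), seed = 42)
  m2 <- newFusionModel(netConfig(1, 4, 4), seed = 42)
  expect_identical(defusion:::collect_params(defusion:::model_nets(m1)),
                   defusion:::collect_params(defusion:::model_nets(m2)))
})

test_that("VGG-style initialization maps and adapts the first three kernels", {
  set.seed(20)
  w <- list(conv1_1 = array(rnorm(3 * 3 * 3 * 64), c(3, 3, 3, 64)),
            conv1_2 = array(rnorm(3 * 3 * 64 * 64), c(3, 3, 64, 64)),
            conv2_1 = array(rnorm(3 * 3 * 64 * 128), c(3, 3, 64, 128)))
  m <- newFusionModel(netConfig(1, 64, 128, useVggInit = TRUE), seed = 21)
  m2 <- initFromVGG(m, w)
  # block 2 kernel equals the second source kernel exactly
  expect_equal(m2@encC1[[2]]$W, matrix(w$conv1_2, 9 * 64, 64))
  expect_equal(m2@encR[[3]]$W, matrix(w$conv2_1, 9 * 64, 128))
  # first-layer kernel is the channel mean of the 3-channel source kernel
  expect_equal(m2@encC2[[1]]$W,
               matrix(apply(w$conv1_1, c(1, 2, 4), mean), 9, 64))
  # decoder untouched
  expect_identical(m2@dec, m@dec)
})

test_that("VGG init is a no-op without the flag and falls back with a warning", {
  m <- tiny_model(seed = 30)
  expect_identical(initFromVGG(m, NULL), m)   # flag off: untouched, silent
  mflag <- newFusionModel(netConfig(1, 4, 4, useVggInit = TRUE), seed = 30)
  expect_warning(m2 <- initFromVGG(mflag, NULL), "unavailable")
  expect_identical(m2@encC1, mflag@encC1)
  expect_warning(initFromVGG(mflag, "/nonexistent/weights.rds"),
                 "unavailable")
})
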