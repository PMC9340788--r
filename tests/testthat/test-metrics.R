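test_that("SD matches closed forms and a loop oracle", {
  expect_equal(metricSD(matrix(0.5, 8, 8)), 0)
  half <- matrix(c(rep(0, 32), rep(1, 32)), 8, 8)
  expect_equal(metricSD(half), 127.5)
  img <- rand_img(1)
  v <- as.vector(img * 255)
  oracle <- sqrt(sum((v - mean(v))^2) / length(v))
  expect_equal(metricSD(img), oracle, tolerance = 1e-9)
  expect_error(metricSD(matrix(numeric(0), 0, 0)), "empty")
})

test_that("SF matches closed forms and a loop oracle", {
  expect_equal(metricSF(matrix(0.3, 8, 8)), 0)
  stripes <- matrix(rep(c(0, 1), 8), 8, 16, byrow = TRUE)[, 1:16]
  # vertical stripes alternate along rows: RF = 255, CF = 0
  stripes <- matrix(0, 8, 16); stripes[, seq(2, 16, 2)] <- 1
  expect_equal(metricSF(stripes), 255)
  img <- rand_img(2)
  v <- img * 255
  rf <- 0; cf <- 0
  for (i in 1:16) for (j in 2:16) rf <- rf + (v[i, j] - v[i, j - 1])^2
  for (i in 2:16) for (j in 1:16) cf <- cf + (v[i, j] - v[i - 1, j])^2
  oracle <- sqrt(rf / (16 * 15) + cf / (16 * 15))
  expect_equal(metricSF(img), oracle, tolerance = 1e-9)
  expect_error(metricSF(matrix(1, 1, 5)), "2 x 2")
})

test_that("Q_MI attains 2 at identity and vanishes for independent images", {
  img <- structured_img()
  expect_equal(metricQMI(img, img, img), 2, tolerance = 1e-9)
  set.seed(3)
  # large-sample independence: enough pixels to overcome histogram bias
  a <- matrix(runif(512 * 512), 512, 512)
  b <- matrix(runif(512 * 512), 512, 512)
  f <- matrix(runif(512 * 512), 512, 512)
  expect_lt(metricQMI(a, b, f), 0.2)
  # symmetric in the sources
  expect_equal(metricQMI(a, b, f), metricQMI(b, a, f))
  # constant image contributes 0 by convention
  h_of <- function(x) defusion:::entropy_nats(
    tabulate(as.vector(defusion:::quantize_bins(x)) + 1, 256) / length(x))
  b2 <- b[1:64, 1:64]; f2 <- f[1:64, 1:64]
  expect_equal(metricQMI(matrix(0.5, 64, 64), b2, f2),
               2 * defusion:::mutual_information(b2, f2) /
                 (h_of(b2) + h_of(f2)),
               tolerance = 1e-9)
})

test_that("Q_NCIE is maximal at identity and matches the eigenvalue oracle", {
  img <- structured_img()
  expect_equal(metricQNCIE(img, img, img), 1, tolerance = 1e-12)
  set.seed(4)
  a <- matrix(runif(512 * 512), 512, 512)
  b <- matrix(runif(512 * 512), 512, 512)
  f <- matrix(runif(512 * 512), 512, 512)
  q_ind <- metricQNCIE(a, b, f)
  expect_lt(q_ind, 1)
  # independent large-sample images: correlation matrix ~ identity, so
  # the closed form approaches 1 - log_256(3)
  expect_equal(q_ind, 1 - log(3) / log(256), tolerance = 0.02)
  expect_equal(metricQNCIE(a, b, f), metricQNCIE(b, a, f))
  # identical triple: R is all ones, eigenvalues (3, 0, 0); oracle check
  R <- matrix(1, 3, 3)
  lam <- eigen(R, symmetric = TRUE)$values
  lam <- lam[lam > 1e-12]
  oracle <- 1 + sum(lam / 3 * log(lam / 3)) / log(256)
  expect_equal(metricQNCIE(img, img, img), oracle)
})

test_that("Q_G rewards exact edge preservation and penalizes flat fusions", {
  img <- structured_img()
  q_same <- metricQG(img, img, img)
  # oracle: G = 1 and A = 1 wherever gradients exist
  cst <- defusion:::QG_CONSTANTS
  qg1 <- cst$gammaG / (1 + exp(cst$kappaG * (1 - cst$sigmaG)))
  qa1 <- cst$gammaA / (1 + exp(cst$kappaA * (1 - cst$sigmaA)))
  expect_equal(q_same, qg1 * qa1, tolerance = 1e-9)
  expect_gt(q_same, 0.95)
  q_flat <- metricQG(img, img, matrix(0.5, 32, 32))
  expect_lt(q_flat, 0.1)
  set.seed(5)
  triples <- replicate(3, metricQG(rand_img(sample(1e4, 1)),
                                   rand_img(sample(1e4, 1)),
                                   rand_img(sample(1e4, 1))))
  expect_true(all(triples >= 0 & triples <= 1))
  expect_equal(metricQG(matrix(0, 8, 8), matrix(0, 8, 8),
                        matrix(0, 8, 8)), 0)    # flat convention
})

test_that("MS-SSIM metric averages both sources", {
  img <- structured_img()
  expect_equal(metricMSSSIM(img, img, img), 1, tolerance = 1e-12)
  binary <- matrix(0, 32, 32); binary[8:24, 8:24] <- 1
  expect_lt(metricMSSSIM(binary, binary, 1 - binary), 0.5)
  a <- structured_img(); b <- 1 - structured_img()
  f <- (a + b) / 2
  expect_equal(metricMSSSIM(a, b, f), metricMSSSIM(b, a, f))
})

test_that("SCD matches the Pearson oracle and its conventions", {
  set.seed(6)
  # zero-mean sources scaled so f = a + b needs no clipping
  a <- 0.5 + (matrix(runif(32 * 32), 32, 32) - 0.5) / 2
  b <- 0.5 + (matrix(runif(32 * 32), 32, 32) - 0.5) / 2
  f <- (a - 0.5) + (b - 0.5) + 0.5
  # each difference equals the other source exactly: both terms are 1
  expect_equal(metricSCD(a, b, f), 2, tolerance = 1e-12)
  # degenerate: f = a makes the first correlation term 0 by convention
  expect_equal(metricSCD(a, b, a), cor(as.vector(a - b), as.vector(a)))
  f2 <- rand_img(7, 32, 32)
  oracle <- cor(as.vector(f2 - a), as.vector(b)) +
    cor(as.vector(f2 - b), as.vector(a))
  expect_equal(metricSCD(a, b, f2), oracle, tolerance = 1e-9)
})

test_that("evaluatePair reports exactly the implemented metrics deterministically", {
  a <- structured_img(); b <- 1 - structured_img()
  f <- (a + b) / 2
  rep1 <- evaluatePair(a, b, f)
  expect_setequal(names(metricValues(rep1)),
                  c("SD", "SF", "QMI", "QNCIE", "QG", "MSSSIM", "SCD"))
  expect_false(any(c("QM", "QS", "QCB", "VIFF") %in%
                     names(metricValues(rep1))))
  rep2 <- evaluatePair(a, b, f)
  expect_identical(metricValues(rep1), metricValues(rep2))
  expect_true(all(is.finite(metricValues(rep1))))
  # CSV and JSON round trips preserve the values
  csv <- file.path(tempdir(), "report.csv")
  json <- file.path(tempdir(), "report.json")
  writeMetricReport(rep1, csv); writeMetricReport(rep1, json)
  expect_equal(readMetricReport(csv), metricValues(rep1))
  expect_equal(readMetricReport(json), metricValues(rep1))
})
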