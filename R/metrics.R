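# Fusion-quality metrics. All functions take images on the internal [0,1]
# scale and convert to the 8-bit [0,255] scale at this boundary, matching
# the magnitudes customary in the fusion literature (e.g. SD around 80 for
# natural brain slices).

to255 <- function(img, name = "image") {
  if (length(img) == 0) stop(name, " is empty")
  img * 255
}

quantize_bins <- function(img, bins = 256) {
  pmin(pmax(floor(img * bins), 0), bins - 1)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

joint_hist <- function(qa, qb, bins = 256) {
  # qa, qb integer matrices in 0..(bins-1)
  idx <- as.vector(qa) * bins + as.vector(qb) + 1
  counts <- tabulate(idx, nbins = bins * bins)
  counts / length(qa)
}

mutual_information <- function(a, b, bins = 256) {
  qa <- quantize_bins(a, bins); qb <- quantize_bins(b, bins)
  pj <- joint_hist(qa, qb, bins)
  pa <- tabulate(as.vector(qa) + 1, nbins = bins) / length(qa)
  pb <- tabulate(as.vector(qb) + 1, nbins = bins) / length(qb)
  entropy_nats(pa) + entropy_nats(pb) - entropy_nats(pj)
}

#' Standard deviation (contrast) of a fused image
#'
#' Population standard deviation of the pixel intensities on the 8-bit
#' scale; reveals the distribution of gray levels.
#'
#' @param fused image matrix in [0,1]
#' @return scalar SD on the [0,255] scale
#' @export
metricSD <- function(fused) {
  v <- to255(fused, "fused")
  sqrt(mean((v - mean(v))^2))
}

#' Spatial frequency (detail) of a fused image
#'
#' sqrt(RF^2 + CF^2) where RF and CF are the root-mean-square horizontal
#' and vertical first differences on the 8-bit scale.
#'
#' @param fused image matrix in [0,1], at least 2 x 2
#' @return scalar SF
#' @export
metricSF <- function(fused) {
  v <- to255(fused, "fused")
  if (nrow(v) < 2 || ncol(v) < 2) stop("image must be at least 2 x 2")
  rf2 <- mean((v[, -1] - v[, -ncol(v)])^2)   # horizontal neighbours
  cf2 <- mean((v[-1, ] - v[-nrow(v), ])^2)   # vertical neighbours
  sqrt(rf2 + cf2)
}

#' Normalized mutual information transfer (Q_MI)
#'
#' Hossny-normalized amount of information transferred from the source
#' images to the fused image:
#' 2 [ MI(a,f)/(H(a)+H(f)) + MI(b,f)/(H(b)+H(f)) ], from 256-bin joint
#' histograms of the 8-bit-quantized images. A zero-entropy (constant)
#' source or fused image contributes 0 to its term.
#'
#' @param a,b source images, matrices in [0,1] of one shape
#' @param fused fused image, same shape
#' @param bins histogram bins (default 256)
#' @return scalar; 2 when f = a = b and near 0 for an unrelated f
#' @export
metricQMI <- function(a, b, fused, bins = 256) {
  if (bins < 2) stop("bins must be >= 2")
  check_same_shape(a, fused, "images"); check_same_shape(b, fused, "images")
  term <- function(src) {
    hs <- entropy_nats(tabulate(as.vector(quantize_bins(src, bins)) + 1,
                                bins) / length(src))
    hf <- entropy_nats(tabulate(as.vector(quantize_bins(fused, bins)) + 1,
                                bins) / length(fused))
    if (hs <= 0 || hf <= 0) return(0)
    mutual_information(src, fused, bins) / (hs + hf)
  }
  2 * (term(a) + term(b))
}

ncc_rank_idx <- function(img, bins = 256) {
  # ascending-rank grouping into `bins` near-equal groups; ties broken by
  # position so identical images get identical (uniform) rank indices
  rk <- rank(as.vector(img), ties.method = "first")
  pmin(ceiling(rk * bins / length(rk)), bins) - 1L
}

#' Nonlinear correlation information entropy (Q_NCIE)
#'
#' Each pairwise nonlinear correlation coefficient is computed from the
#' rank-grouped 256x256 joint histogram, NCC = H_b(X) + H_b(Y) -
#' H_b(X,Y) with base-b logarithms (b = 256), giving 1 for identical and
#' about 0 for independent images. Q_NCIE = 1 + sum_i (lambda_i/3)
#' log_b(lambda_i/3) over the eigenvalues of the 3x3 NCC matrix of
#' (a, b, f); values lie in (0, 1]. A constant image has no rank
#' structure, so its off-diagonal coefficients are set to 0.
#'
#' @param a,b source images, matrices in [0,1] of one shape
#' @param fused fused image, same shape
#' @return scalar in (0, 1]
#' @export
metricQNCIE <- function(a, b, fused) {
  check_same_shape(a, fused, "images"); check_same_shape(b, fused, "images")
  bins <- 256
  imgs <- list(a, b, fused)
  constant <- vapply(imgs, function(x) diff(range(x)) == 0, logical(1))
  idx <- lapply(imgs, ncc_rank_idx, bins = bins)
  ncc <- function(i, j) {
    if (constant[i] || constant[j]) return(0)
    pj <- joint_hist(idx[[i]], idx[[j]], bins)
    pi_ <- tabulate(idx[[i]] + 1, bins) / length(idx[[i]])
    pj_ <- tabulate(idx[[j]] + 1, bins) / length(idx[[j]])
    (entropy_nats(pi_) + entropy_nats(pj_) - entropy_nats(pj)) / log(bins)
  }
  R <- diag(3)
  for (i in 1:2) for (j in (i + 1):3) R[i, j] <- R[j, i] <- ncc(i, j)
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 0]
  1 + sum(lam / 3 * log(lam / 3)) / log(bins)
}

sobel_grad <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dx (columns)
  ky <- t(kx)                                            # d/dy (rows)
  H <- nrow(img); W <- ncol(img)
  # replicate-padding: constant images get zero gradient at the borders
  pad <- img[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  cube <- array(pad, c(dim(pad), 1))
  keep <- function(m) m[1 + seq_len(H), 1 + seq_len(W)]
  sx <- keep(cpp_conv3_fwd(cube, matrix(as.vector(kx), 9, 1), 0)[, , 1])
  sy <- keep(cpp_conv3_fwd(cube, matrix(as.vector(ky), 9, 1), 0)[, , 1])
  list(g = sqrt(sx^2 + sy^2), alpha = atan2(sy, sx))
}

QG_CONSTANTS <- list(gammaG = 0.9994, kappaG = -15, sigmaG = 0.5,
                     gammaA = 0.9879, kappaA = -22, sigmaA = 0.8, L = 1)

#' Gradient-based fusion performance (Q_G / Q^AB/F)
#'
#' Edge-preservation score: Sobel gradient strength and orientation are
#' compared between each source and the fused image, mapped through the
#' standard sigmoid preservation curves (Gamma_g = 0.9994, kappa_g = -15,
#' sigma_g = 0.5; Gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8) and
#' averaged with gradient-strength weights (exponent L = 1). Pixels where
#' both gradients vanish contribute zero preservation; if both sources are
#' completely flat the score is defined as 0.
#'
#' @param a,b source images, matrices in [0,1] of one shape
#' @param fused fused image, same shape
#' @return scalar in [0,1]
#' @export
metricQG <- function(a, b, fused) {
  check_same_shape(a, fused, "images"); check_same_shape(b, fused, "images")
  cst <- QG_CONSTANTS
  gf <- sobel_grad(to255(fused, "fused"))
  pres <- function(src) {
    gs <- sobel_grad(to255(src, "source"))
    hi <- pmax(gs$g, gf$g); lo <- pmin(gs$g, gf$g)
    G <- ifelse(hi > 0, lo / hi, 0)
    A <- 1 - abs(gs$alpha - gf$alpha) %% pi / (pi / 2)
    A <- abs(A)      # wrap orientation difference into [0, pi/2]
    Qg <- cst$gammaG / (1 + exp(cst$kappaG * (G - cst$sigmaG)))
    Qa <- cst$gammaA / (1 + exp(cst$kappaA * (A - cst$sigmaA)))
    list(q = Qg * Qa, w = gs$g^cst$L)
  }
  pa <- pres(a); pb <- pres(b)
  denom <- sum(pa$w + pb$w)
  if (denom == 0) return(0)
  sum(pa$q * pa$w + pb$q * pb$w) / denom
}

#' Multi-scale structural similarity of a fusion triple
#'
#' Mean of MS-SSIM(a, f) and MS-SSIM(b, f) with the standard 5-scale
#' weights (see \code{\link{msssimIndex}}).
#'
#' @param a,b source images, matrices in [0,1], min dimension >= 32
#' @param fused fused image, same shape
#' @return scalar, 1 when f = a = b
#' @export
metricMSSSIM <- function(a, b, fused) {
  check_same_shape(a, fused, "images"); check_same_shape(b, fused, "images")
  (msssimIndex(a, fused) + msssimIndex(b, fused)) / 2
}

safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Sum of correlations of differences (SCD)
#'
#' corr(f - a, b) + corr(f - b, a): how much of each source's complement
#' appears in the fused image. A zero-variance difference contributes 0.
#'
#' @param a,b source images, matrices in [0,1] of one shape
#' @param fused fused image, same shape
#' @return scalar in [-2, 2]
#' @export
metricSCD <- function(a, b, fused) {
  check_same_shape(a, fused, "images"); check_same_shape(b, fused, "images")
  safe_cor(as.vector(fused - a), as.vector(b)) +
    safe_cor(as.vector(fused - b), as.vector(a))
}

#' Evaluate all implemented metrics on a fusion triple
#'
#' Computes SD, SF, Q_MI, Q_NCIE, Q_G, MS-SSIM and SCD with their
#' parameters recorded. Metrics specified only in third-party papers
#' (Q_M, Q_S, Q_CB, VIFF) are not computed and their keys are absent.
#'
#' @param a,b source images, matrices in [0,1] of one shape
#' @param fused fused image, same shape
#' @param images optional identifiers recorded in the report
#' @return a \code{\linkS4class{MetricReport}}
#' @export
evaluatePair <- function(a, b, fused, images = c("img1", "img2", "fused")) {
  vals <- c(SD = metricSD(fused), SF = metricSF(fused),
            QMI = metricQMI(a, b, fused), QNCIE = metricQNCIE(a, b, fused),
            QG = metricQG(a, b, fused), MSSSIM = metricMSSSIM(a, b, fused),
            SCD = metricSCD(a, b, fused))
  new("MetricReport", values = vals,
      params = c(list(histogramBins = 256, ssimWindow = SSIM_WIN,
                      ssimSigma = SSIM_SIGMA, msssimWeights = MSSSIM_WEIGHTS,
                      intensityScale = "0-255"), QG_CONSTANTS),
      images = as.character(images))
}

#' Write a metric report to CSV or JSON
#'
#' @param report a \code{\linkS4class{MetricReport}}
#' @param path output file; format follows the extension (.csv or .json)
#' @return the path, invisibly
#' @export
writeMetricReport <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(values = as.list(report@values),
                              params = report@params,
                              images = report@images),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(data.frame(metric = names(report@values),
                         value = unname(report@values)),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a metric report written by \code{\link{writeMetricReport}}
#'
#' @param path a .csv or .json report file
#' @return named numeric vector of metric values
#' @export
readMetricReport <- function(path) {
  if (grepl("\\.json$", path)) {
    v <- jsonlite::read_json(path, simplifyVector = TRUE)$values
    unlist(v)
  } else {
    d <- read.csv(path)
    stats::setNames(d$value, d$metric)
  }
}
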