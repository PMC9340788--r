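# The training objective: complementary group-lasso penalty with adaptive
# sigmoid weights, redundant consistency constraint, and the MSE + SSIM
# reconstruction loss. Exported functions operate on single H x W x V
# feature maps / single images; the batched gradient versions used by the
# training loop live at the bottom.

as_feature <- function(C, name = "feature map") {
  if (is.matrix(C)) C <- array(C, c(dim(C), 1))
  if (!is.array(C) || length(dim(C)) != 3)
    stop(name, " must be an H x W x V array")
  C
}

feat_mat <- function(C) matrix(C, prod(dim(C)[1:2]), dim(C)[3])

#' Per-position cosine similarity of two feature maps
#'
#' At every spatial position the cosine of the angle between the two
#' V-channel vectors. Positions where either vector has zero norm yield
#' similarity 0: an all-zero feature carries no redundancy, so it is
#' treated as maximally complementary.
#'
#' @param C1,C2 H x W x V feature arrays of one shape
#' @return H x W matrix with values in [-1, 1]
#' @export
cosineSimilarityMap <- function(C1, C2) {
  C1 <- as_feature(C1, "C1"); C2 <- as_feature(C2, "C2")
  if (!identical(dim(C1), dim(C2))) stop("C1 and C2 must share one shape")
  m1 <- feat_mat(C1); m2 <- feat_mat(C2)
  n1 <- sqrt(rowSums(m1 * m1)); n2 <- sqrt(rowSums(m2 * m2))
  r <- rowSums(m1 * m2)
  nz <- n1 > 0 & n2 > 0
  r[nz] <- r[nz] / (n1[nz] * n2[nz])
  r[!nz] <- 0
  matrix(pmin(pmax(r, -1), 1), dim(C1)[1], dim(C1)[2])
}

#' Per-position channel L1 norm of a feature map
#'
#' @param C H x W x V feature array
#' @return H x W matrix of L1 norms over the channel dimension
#' @export
channelL1Map <- function(C) {
  C <- as_feature(C)
  matrix(rowSums(abs(feat_mat(C))), dim(C)[1], dim(C)[2])
}

#' Local feature importance
#'
#' Mean of the channel-L1 map over the (2r+1) x (2r+1) block centered at
#' each position. The denominator is fixed at (2r+1)^2 everywhere with
#' zero padding outside the image, matching a plain block-sum formula, so
#' border positions are attenuated.
#'
#' @param cHat H x W channel-L1 map (see \code{\link{channelL1Map}})
#' @param radius block radius r >= 0 (default 1, a 3x3 block)
#' @return H x W importance map
#' @export
localImportance <- function(cHat, radius = 1) {
  if (radius < 0 || radius != round(radius))
    stop("radius must be a non-negative integer")
  if (radius == 0) return(cHat)
  k <- rep(1 / (2 * radius + 1), 2 * radius + 1)
  cpp_sepfilter(cHat, k, 0L)
}

#' Sigmoid steepness from feature similarity
#'
#' k = 1 / max(similarity^2, epsilon). Low similarity (complementary
#' content) gives a steep sigmoid, pushing the weight assignment towards
#' choose-max; high similarity (redundant content) gives k near 1 and
#' near-average weighting. The epsilon floor bounds k (default <= 1e4) and
#' removes the singularity at zero similarity.
#'
#' @param similarity cosine similarity value(s) in [-1, 1]
#' @param epsilon positive floor for similarity^2 (default 1e-4)
#' @return steepness value(s) in [1, 1/epsilon]
#' @export
steepnessK <- function(similarity, epsilon = 1e-4) {
  if (any(abs(similarity) > 1 + 1e-9)) stop("|similarity| must be <= 1")
  1 / pmax(similarity^2, epsilon)
}

#' Adaptive penalty weights for the complementary group lasso
#'
#' omega1 = 1 / (1 + exp(k (phi1 - phi2))), omega2 = 1 - omega1: when
#' phi1 >> phi2 (the modality-1 feature is locally the more important one)
#' omega1 tends to zero, so less penalty is imposed on C1 while C2 is
#' filtered out of the complementary maps, and vice versa. Equal
#' importances give exact 0.5/0.5. \code{flipSign = TRUE} flips the
#' exponent's sign, which reverses which feature is spared.
#'
#' @param phi1,phi2 local importance value(s) (see
#'   \code{\link{localImportance}})
#' @param k sigmoid steepness > 0 (see \code{\link{steepnessK}})
#' @param flipSign use the flipped-sign convention (default FALSE)
#' @return list with \code{omega1}, \code{omega2}, each in (0, 1) except
#'   for exact saturation at extreme k * (phi1 - phi2)
#' @export
penaltyWeights <- function(phi1, phi2, k, flipSign = FALSE) {
  if (any(k <= 0)) stop("k must be > 0")
  d <- if (flipSign) phi2 - phi1 else phi1 - phi2
  # saturate at the double-precision boundary: weights stay strictly
  # inside (0,1) and never overflow
  e <- pmin(pmax(k * d, -36), 36)
  w1 <- 1 / (1 + exp(e))
  list(omega1 = w1, omega2 = 1 - w1)
}

lc_internal <- function(C1, C2, config, with_grad = FALSE) {
  m1 <- feat_mat(C1); m2 <- feat_mat(C2)
  H <- dim(C1)[1]; W <- dim(C1)[2]; P <- H * W
  n1 <- sqrt(rowSums(m1 * m1)); n2 <- sqrt(rowSums(m2 * m2))
  r <- as.vector(cosineSimilarityMap(C1, C2))
  k <- steepnessK(r, config@similarityEpsilon)
  phi1 <- localImportance(channelL1Map(C1), config@blockRadius)
  phi2 <- localImportance(channelL1Map(C2), config@blockRadius)
  w <- penaltyWeights(phi1, phi2, k, config@flipSign)
  w1 <- as.vector(w$omega1); w2 <- as.vector(w$omega2)
  P <- if (config@lcNormalization == "mean") P else 1
  lc <- sum(w1 * n1 + w2 * n2) / P
  if (!with_grad) return(lc)
  # group-norm path: d||C||_2/dC = C/||C||_2 (subgradient 0 at 0)
  g1 <- m1 * (ifelse(n1 > 0, w1 / n1, 0) / P)
  g2 <- m2 * (ifelse(n2 > 0, w2 / n2, 0) / P)
  if (!config@detachWeights) {
    # chain rule through the weights: e = k * s * (phi1 - phi2),
    # omega1 = sigmoid(-e), dLc/de = -omega1 omega2 (n1 - n2) / P
    sgn <- if (config@flipSign) -1 else 1
    d <- sgn * as.vector(phi1 - phi2)
    e <- k * d
    ge <- ifelse(abs(e) < 36, -w1 * w2 * (n1 - n2) / P, 0)
    # ... through the importances (box filter is self-adjoint)
    box <- function(v) as.vector(localImportance(matrix(v, H, W),
                                                 config@blockRadius))
    gphi <- box(ge * k) * sgn
    g1 <- g1 + sign(m1) * gphi
    g2 <- g2 - sign(m2) * gphi
    # ... through the steepness k = 1/max(r^2, eps)
    act <- r^2 > config@similarityEpsilon & n1 > 0 & n2 > 0
    gr <- ifelse(act, ge * d * (-2 / r^3), 0)
    gc1 <- m2 / (n1 * n2) - m1 * (r / n1^2)
    gc2 <- m1 / (n1 * n2) - m2 * (r / n2^2)
    gc1[!act, ] <- 0; gc2[!act, ] <- 0
    g1 <- g1 + gc1 * gr
    g2 <- g2 + gc2 * gr
  }
  list(value = lc, g1 = array(g1, dim(C1)), g2 = array(g2, dim(C2)))
}

#' Complementary group-lasso penalty
#'
#' The channel vector at each spatial position of a complementary feature
#' map is one group; the penalty is the importance-weighted sum of the two
#' groups' L2 norms, averaged over positions:
#' \code{sum(omega1 ||C1(x,y)||_2 + omega2 ||C2(x,y)||_2)}. The weights
#' come from \code{\link{penaltyWeights}} with per-position steepness
#' \code{\link{steepnessK}} and are treated as constants in
#' backpropagation when \code{config@detachWeights} is set. By default
#' the penalty is summed over positions; at the default lambdaC = 10
#' the per-position pull is then strong enough to drive locally
#' unimportant groups to exact zero (the filtering the penalty exists
#' for), where a mean normalization would only shrink them
#' (\code{lcNormalization = "mean"} remains available).
#'
#' @param C1,C2 H x W x V complementary feature arrays of one shape
#' @param config a \code{\link{lossConfig}}
#' @return scalar penalty >= 0; zero iff both maps are identically zero
#' @export
complementaryGroupLasso <- function(C1, C2, config = lossConfig()) {
  C1 <- as_feature(C1, "C1"); C2 <- as_feature(C2, "C2")
  if (!identical(dim(C1), dim(C2))) stop("C1 and C2 must share one shape")
  lc_internal(C1, C2, config)
}

#' Redundant consistency constraint
#'
#' Mean absolute difference between the decodings of the two redundant
#' feature maps, De_S(R1) and De_S(R2). Constraining the decoded results
#' rather than the features themselves tolerates the unequal amount of
#' information the two modalities carry.
#'
#' @param model a \code{\linkS4class{FusionModel}}
#' @param R1,R2 H x W x V redundant feature arrays of one shape
#' @return scalar mean per-pixel L1 difference
#' @export
redundantConsistency <- function(model, R1, R2) {
  R1 <- as_feature(R1, "R1"); R2 <- as_feature(R2, "R2")
  if (!identical(dim(R1), dim(R2))) stop("R1 and R2 must share one shape")
  mean(abs(decodeFeatures(model, R1) - decodeFeatures(model, R2)))
}

#' Reconstruction loss of the four decode targets
#'
#' Sums per-pair mean squared error and (1 - SSIM) over the four
#' reconstruction pairs: the self-reconstructions against their own source
#' and the cross-reconstructions against the image that provided the
#' complementary features. \code{lRec = lambdaSsim * lSsim + lMse}. MSE is
#' the per-pixel mean, so lambdaSsim = 1000 balances quantities of order
#' at most one regardless of image size.
#'
#' @param I1,I2 source images (matrices in [0,1])
#' @param I1hat,I2hat self-reconstructions of I1, I2
#' @param I12hat,I21hat cross-reconstructions targeting I1, I2
#' @param config a \code{\link{lossConfig}}
#' @return list with scalars \code{lMse}, \code{lSsim}, \code{lRec}
#' @export
reconstructionLoss <- function(I1, I2, I1hat, I12hat, I2hat, I21hat,
                               config = lossConfig()) {
  outs <- list(I1hat, I12hat, I2hat, I21hat)
  tgts <- list(I1, I1, I2, I2)
  for (o in outs)
    if (!identical(dim(o), dim(I1)))
      stop("all images must share one shape")
  lmse <- sum(vapply(1:4, function(i) mean((outs[[i]] - tgts[[i]])^2),
                     numeric(1)))
  lssim <- sum(vapply(1:4, function(i) 1 - ssimIndex(tgts[[i]], outs[[i]]),
                      numeric(1)))
  list(lMse = lmse, lSsim = lssim, lRec = config@lambdaSsim * lssim + lmse)
}

#' Assemble the weighted total training objective
#'
#' \code{total = lRec + lambdaR * lR + lambdaC * lC} with
#' \code{lRec = lambdaSsim * lSsim + lMse}; all components are stored for
#' logging.
#'
#' @param lMse,lSsim,lR,lC component scalars (>= 0, finite)
#' @param config a \code{\link{lossConfig}}
#' @return a \code{\linkS4class{LossBreakdown}}
#' @export
totalLoss <- function(lMse, lSsim, lR, lC, config = lossConfig()) {
  comp <- c(lMse = lMse, lSsim = lSsim, lR = lR, lC = lC)
  if (any(!is.finite(comp)))
    stop("non-finite loss component: ",
         paste(names(comp)[!is.finite(comp)], collapse = ", "))
  lrec <- config@lambdaSsim * lSsim + lMse
  new("LossBreakdown", lMse = lMse, lSsim = lSsim, lRec = lrec,
      lR = lR, lC = lC,
      total = lrec + config@lambdaR * lR + config@lambdaC * lC)
}
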