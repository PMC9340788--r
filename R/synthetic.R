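# Synthetic paired-modality generator. Each pair shares an anatomical
# structure S (smooth ellipse/blob union with internal edges, mimicking a
# brain slice) and adds a modality-unique component: band-limited stripe
# texture for the MRI-like modality, dense bright convex blobs for the
# CT-like modality. The ground-truth decomposition is retained so
# disentanglement is measurable. Everything is bit-reproducible from
# (seed, params).

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

ellipse_mask <- function(gx, gy, xc, yc, a, b, theta) {
  u <- (gx - xc) * cos(theta) + (gy - yc) * sin(theta)
  v <- -(gx - xc) * sin(theta) + (gy - yc) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a shared anatomical structure image
#'
#' A smooth closed region (union of ellipses) with internal edges:
#' an outer boundary, a few internal substructures of differing intensity
#' and a darker ventricle-like cavity, lightly smoothed. Deterministic
#' given the seed.
#'
#' @param seed integer seed
#' @param size c(H, W), both at least 32
#' @return H x W matrix with values in [0,1]
#' @export
makeSharedStructure <- function(seed, size = c(64, 64)) {
  if (length(size) != 2 || any(size < 32))
    stop("size must be c(H, W) with H, W >= 32")
  H <- size[1]; W <- size[2]
  with_seed(seed, {
    gx <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    gy <- matrix(seq(-1, 1, length.out = H), H, W)
    S <- matrix(0, H, W)
    outer_a <- runif(1, 0.72, 0.88); outer_b <- runif(1, 0.6, 0.8)
    th0 <- runif(1, -0.3, 0.3)
    S[ellipse_mask(gx, gy, 0, 0, outer_a, outer_b, th0)] <- 0.55
    for (i in 1:3) {                      # internal substructures
      m <- ellipse_mask(gx, gy, runif(1, -0.35, 0.35), runif(1, -0.35, 0.35),
                        runif(1, 0.12, 0.3), runif(1, 0.1, 0.25),
                        runif(1, 0, pi))
      S[m & S > 0] <- runif(1, 0.35, 0.95)
    }
    vent <- ellipse_mask(gx, gy, runif(1, -0.1, 0.1), runif(1, -0.1, 0.1),
                         runif(1, 0.08, 0.16), runif(1, 0.15, 0.3),
                         runif(1, -0.4, 0.4))
    S[vent & S > 0] <- 0.15
    k <- gauss_kernel(5, 1)
    pmin(pmax(cpp_sepfilter(S, k, 1L), 0), 1)
  })
}

default_pair_params <- function() {
  list(a1 = 0.6, b1 = 0.4,        # I1 = clip(a1 S + b1 U1)
       a2 = 0.6, b2 = 0.4,        # I2 = clip(a2 S + b2 U2)
       textureFreq = 8,           # stripe cycles across the image width
       nBlobs = 6, blobRadius = 0.07,
       maxOverlap = 0.1,          # tolerated U1/U2 support overlap fraction
       withColor = FALSE)
}

#' Generate one synthetic co-registered modality pair
#'
#' Builds a shared structure S, a stripe-texture unique component U1 and a
#' bright-blob unique component U2 with weakly overlapping supports (U1
#' occupies one side of a random dividing direction, the blob centers the
#' other; the realized overlap fraction is recorded in \code{params}),
#' then mixes \code{I1 = clip(a1 S + b1 U1)} and
#' \code{I2 = clip(a2 S + b2 U2)}. With \code{withColor = TRUE} an RGB
#' companion of I2 is produced by a fixed perceptual colormap
#' (black-purple-red-yellow-white), mimicking a pseudo-colored PET
#' display.
#'
#' @param seed integer seed
#' @param size c(H, W), both at least 32
#' @param params named list overriding \code{default_pair_params()}:
#'   mixing coefficients a1, b1, a2, b2 >= 0, textureFreq > 0, nBlobs >= 1,
#'   blobRadius in (0, 0.5), maxOverlap in [0,1], withColor flag
#' @return a \code{\linkS4class{SyntheticPair}}
#' @export
makePair <- function(seed, size = c(64, 64), params = list()) {
  p <- modifyList(default_pair_params(), params)
  bad <- !names(params) %in% names(default_pair_params())
  if (any(bad)) stop("unknown params: ", paste(names(params)[bad],
                                               collapse = ", "))
  with(p, {
    if (any(c(a1, b1, a2, b2) < 0)) stop("mixing coefficients must be >= 0")
    if (textureFreq <= 0 || nBlobs < 1 || blobRadius <= 0 || blobRadius >= 0.5)
      stop("invalid texture/blob params")
  })
  S <- makeSharedStructure(seed, size)
  H <- size[1]; W <- size[2]
  with_seed(seed + 1L, {
    gx <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    gy <- matrix(seq(-1, 1, length.out = H), H, W)
    inside <- S > 0.05
    # random dividing direction: texture on one side, blobs on the other
    phi <- runif(1, 0, 2 * pi)
    side <- gx * cos(phi) + gy * sin(phi)
    th <- runif(1, 0, pi); phase <- runif(1, 0, 2 * pi)
    stripes <- sin(2 * pi * p$textureFreq *
                     (gx * cos(th) + gy * sin(th)) / 2 + phase)
    U1 <- pmax(stripes, 0) * inside * (side > 0.05)
    U2 <- matrix(0, H, W)
    cand <- which(inside & side < -0.05, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      idx <- cand[sample.int(nrow(cand), min(p$nBlobs, nrow(cand))), ,
                  drop = FALSE]
      for (i in seq_len(nrow(idx))) {
        cy <- gy[idx[i, 1], 1]; cx <- gx[1, idx[i, 2]]
        d2 <- (gx - cx)^2 + (gy - cy)^2
        U2 <- pmax(U2, exp(-d2 / (2 * (p$blobRadius / 2)^2)))
      }
      U2[U2 < 0.05] <- 0
    }
    s1 <- U1 > 0; s2 <- U2 > 0
    overlap <- if (any(s1) && any(s2))
      sum(s1 & s2) / min(sum(s1), sum(s2)) else 0
    I1 <- pmin(pmax(p$a1 * S + p$b1 * U1, 0), 1)
    I2 <- pmin(pmax(p$a2 * S + p$b2 * U2, 0), 1)
    col2 <- if (p$withColor) pseudocolor(I2) else NULL
    p$overlap <- overlap
    new("SyntheticPair", I1 = I1, I2 = I2, shared = S,
        unique1 = U1, unique2 = U2, color2 = col2,
        seed = as.numeric(seed), params = p)
  })
}

pet_ramp <- local({
  f <- NULL
  function() {
    if (is.null(f))
      f <<- grDevices::colorRamp(c("black", "#4B0082", "red", "yellow",
                                   "white"))
    f
  }
})

#' Map a grayscale image through the fixed PET-like colormap
#'
#' @param img matrix in [0,1]
#' @return H x W x 3 RGB array in [0,1]
#' @export
pseudocolor <- function(img) {
  rgb <- pet_ramp()(as.vector(img)) / 255
  array(rgb, c(dim(img), 3))
}

#' Generate a reproducible synthetic dataset
#'
#' Pair seeds are derived deterministically from the master seed, so the
#' same call yields a bitwise-identical dataset. When \code{dir} is given
#' the pairs are also written as 8-bit PNGs (modalities, optional RGB
#' companion and ground-truth arrays) together with a JSON manifest; see
#' \code{\link{writeDataset}}.
#'
#' @param n number of pairs (>= 1)
#' @param seed master seed
#' @param size c(H, W) passed to \code{\link{makePair}}
#' @param params generator parameters passed to \code{\link{makePair}}
#' @param dir optional output directory
#' @return list of \code{\linkS4class{SyntheticPair}} (invisibly when
#'   written to \code{dir})
#' @export
makeDataset <- function(n, seed = 1, size = c(64, 64), params = list(),
                        dir = NULL) {
  if (n < 1) stop("n must be >= 1")
  seeds <- (as.numeric(seed) + 9973 * seq_len(n)) %% 2147483647
  pairs <- lapply(seeds, makePair, size = size, params = params)
  if (!is.null(dir)) {
    writeDataset(pairs, dir, seed = seed)
    return(invisible(pairs))
  }
  pairs
}
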