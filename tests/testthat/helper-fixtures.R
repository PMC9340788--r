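# Shared fixtures: everything is generated in code at test time.

rand_feat <- function(seed, H = 8, W = 8, V = 4, lo = 0, hi = 1) {
  set.seed(seed)
  array(runif(H * W * V, lo, hi), c(H, W, V))
}

rand_img <- function(seed, H = 16, W = 16) {
  set.seed(seed)
  matrix(runif(H * W), H, W)
}

tiny_model <- function(seed = 1, channels = 4) {
  newFusionModel(netConfig(1, channels, channels), seed = seed)
}

# structured test image: smooth gradient + a bright square (non-trivial
# edges and histogram)
structured_img <- function(H = 32, W = 32) {
  img <- outer(seq(0, 0.6, length.out = H), seq(0, 0.6, length.out = W),
               function(a, b) (a + b) / 2)
  img[10:20, 10:20] <- 0.9
  img
}
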