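# Shared fixtures: separable Gaussian blur (replicate border), synthetic
# power-law spectrum blocks, and small phantom pair factories.

gaussian_blur <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(v) c(rep(v[1], r), v, rep(v[length(v)], r))
  conv1 <- function(v) stats::convolve(pad(v), rev(k), type = "filter")
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}

# real random-phase field with per-coefficient |spectrum| ~ f^(-a0),
# rescaled to [0, 1]
alpha_block <- function(n, a0, seed) {
  set.seed(seed)
  fi <- c(0:(n %/% 2), rev(seq_len(n - n %/% 2 - 1)))
  rad <- sqrt(outer(fi^2, fi^2, "+"))
  mag <- ifelse(rad == 0, 0, rad^(-a0))
  ph <- matrix(runif(n * n, 0, 2 * pi), n)
  blk <- Re(stats::fft(mag * exp(1i * ph), inverse = TRUE)) / n^2
  (blk - min(blk)) / (max(blk) - min(blk))
}

flat_phantom_cfg <- function(seed = 7L, h = 64L, w = 64L)
  phantom_config(height = h, width = w, n_layers = 3L,
                 layer_intensities = c(0.1, 0.6, 0.3),
                 boundary_waviness = 0, foveal_dip = 0,
                 vessel_shadows = 0L, seed = seed)

# merge patch sets from several pairs into one training set
merge_patch_sets <- function(pairs, protocol) {
  psets <- lapply(pairs, extract_patches, protocol = protocol)
  merged <- list(
    noisy = octsharp:::abind4(lapply(psets, `[[`, "noisy")),
    reference = octsharp:::abind4(lapply(psets, `[[`, "reference")),
    corners = do.call(rbind, lapply(psets, `[[`, "corners")))
  class(merged) <- "patch_set"
  merged
}

toy_training_set <- function(n_pairs = 4, h = 160, w = 160, patch = 40L,
                             stride = 20L, looks = 4, n_frames = 8L,
                             seed_base = 0L) {
  pairs <- lapply(seq_len(n_pairs), function(i)
    synthesize_pair(phantom_config(height = h, width = w,
                                   seed = seed_base + i),
                    speckle_config(looks = looks, n_frames = n_frames,
                                   seed = seed_base + 100L + i)))
  prot <- patch_protocol(patch = patch, stride = stride)
  list(patches = filter_patches(merge_patch_sets(pairs, prot), prot),
       pairs = pairs, protocol = prot)
}
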