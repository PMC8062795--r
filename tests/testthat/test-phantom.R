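test_that("phantom configs are validated", {
  expect_error(phantom_config(n_layers = 1, layer_intensities = 0.5),
               "at least 2 bands")
  expect_error(phantom_config(n_layers = 2,
                              layer_intensities = c(0.5, 1.2)),
               "\\[0, 1\\]")
  expect_error(phantom_config(n_layers = 3,
                              layer_intensities = c(0.1, 0.2)),
               "one value per band")
  expect_error(speckle_config(looks = 0), "looks")
  expect_error(speckle_config(n_frames = 0), "n_frames")
})

test_that("noiseless phantom is piecewise constant away from boundaries", {
  ph <- generate_phantom(flat_phantom_cfg())
  vals <- ph$image$pixels
  # rows touched by anti-aliased boundary pixels
  brows <- unique(unlist(lapply(ph$boundaries, function(b)
    c(floor(b), ceiling(b)) + 1)))
  interior <- vals[setdiff(seq_len(nrow(vals)), brows), ]
  expect_setequal(round(unique(as.vector(interior)), 10), c(0.1, 0.6, 0.3))
})

test_that("identical config and seed give bit-identical phantoms", {
  cfg <- phantom_config(seed = 7L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$boundaries, b$boundaries)
})

test_that("boundary sets are ordered and inside the image", {
  for (seed in 1:5) {
    cfg <- phantom_config(seed = seed)
    ph <- generate_phantom(cfg)
    B <- do.call(cbind, ph$boundaries)
    expect_equal(ncol(B), cfg$n_layers - 1L)
    expect_true(all(B >= 0 & B < cfg$height))
    expect_true(all(apply(B, 1, diff) > 0))   # top-to-bottom order per column
    expect_true(all(vapply(ph$boundaries, length, 1L) == cfg$width))
  }
})

test_that("excessive waviness that would cross boundaries is rejected", {
  cfg <- phantom_config(height = 64, width = 64, n_layers = 6,
                        boundary_waviness = 30, seed = 3)
  expect_error(generate_phantom(cfg), "cross|leave")
})

test_that("speckle has gamma number-of-looks moments", {
  flat <- image_plane(matrix(0.5, 512, 512))
  sp <- apply_speckle(flat, speckle_config(looks = 4, seed = 3), 0)
  expect_lt(abs(mean(sp$pixels) - 0.5), 0.005)            # unit mean, 1%
  expect_lt(abs(var(as.vector(sp$pixels)) - 0.0625), 0.0031)  # mu^2/L, 5%
})

test_that("zero image stays zero and infinite looks recover the input", {
  z <- apply_speckle(image_plane(matrix(0, 32, 32)),
                     speckle_config(looks = 4, seed = 1), 0)
  expect_true(all(z$pixels == 0))
  near <- apply_speckle(image_plane(matrix(0.5, 64, 64)),
                        speckle_config(looks = 1e6, seed = 1), 0)
  expect_lt(max(abs(near$pixels - 0.5)), 0.01)
})

test_that("speckle frames are independent and individually reproducible", {
  flat <- image_plane(matrix(0.5, 64, 64))
  cfg <- speckle_config(looks = 4, seed = 9)
  f0 <- apply_speckle(flat, cfg, 0)
  f1 <- apply_speckle(flat, cfg, 1)
  expect_false(isTRUE(all.equal(f0$pixels, f1$pixels)))
  expect_identical(apply_speckle(flat, cfg, 1)$pixels, f1$pixels)
  expect_lt(abs(cor(as.vector(f0$pixels), as.vector(f1$pixels))), 0.02)
})

test_that("frame averaging follows the 1/K variance law", {
  pc <- flat_phantom_cfg(h = 128, w = 128)
  pair <- synthesize_pair(
    phantom_config(height = 128, width = 128, n_layers = 2,
                   layer_intensities = c(0.5, 0.5), boundary_waviness = 0,
                   foveal_dip = 0, vessel_shadows = 0, seed = 4),
    speckle_config(looks = 4, n_frames = 16, seed = 4))
  v <- var(as.vector(pair$reference$pixels))
  expect_lt(abs(v - 0.25 / (4 * 16)), 0.1 * 0.25 / (4 * 16))
})

test_that("averaged reference is closer to clean than the noisy frame", {
  pair <- synthesize_pair(phantom_config(seed = 2),
                          speckle_config(looks = 4, n_frames = 4, seed = 2))
  expect_gt(psnr(pair$reference, pair$clean), psnr(pair$noisy, pair$clean))
  expect_identical(dim(pair$noisy), dim(pair$reference))
})
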