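test_that("dncnn roster follows the three layer types", {
  m <- build_dncnn(dncnn_config(depth = 17, width = 64), seed = 1)
  types <- vapply(m$layers, `[[`, character(1), "type")
  convs <- which(types == "conv")
  expect_length(convs, 17L)                       # 17 weight layers
  expect_equal(types[1:2], c("conv", "relu"))     # Conv+ReLU in
  expect_equal(types[length(types)], "conv")      # bare Conv out
  expect_equal(sum(types == "bn"), 15L)           # BN on all hidden layers
  expect_equal(dim(m$layers[[convs[2]]]$w), c(3, 3, 64, 64))
  expect_equal(dim(m$layers[[convs[17]]]$w)[4], 1L)  # single output filter
  expect_error(dncnn_config(depth = 2), "depth")
})

test_that("toy configs build, run, and count parameters by hand", {
  m <- build_dncnn(dncnn_config(depth = 8, width = 32), seed = 2)
  out <- denoise(m, matrix(runif(40 * 40), 40))
  expect_equal(dim(out$pixels), c(40, 40))
  # depth 3 / width 4 / kernel 3: conv(1->4)+b, conv(4->4)+b + BN(2*4),
  # conv(4->1)+b  =  40 + 156 + 37
  m3 <- build_dncnn(dncnn_config(depth = 3, width = 4), seed = 1)
  expect_identical(n_parameters(m3),
                   (1 * 4 * 9 + 4) + (4 * 4 * 9 + 4 + 2 * 4) +
                     (4 * 1 * 9 + 1))
})

test_that("zero residual weights give the identity mapping", {
  m <- build_dncnn(dncnn_config(depth = 3, width = 4), seed = 1)
  m$layers <- lapply(m$layers, function(l) {
    if (l$type == "conv") { l$w[] <- 0; if (!is.null(l$b)) l$b[] <- 0 }
    l
  })
  img <- image_plane(matrix(runif(180 * 180), 180))
  expect_identical(denoise(m, img)$pixels, img$pixels)
})

test_that("denoising preserves arbitrary input shapes", {
  m <- build_dncnn(dncnn_config(depth = 3, width = 4), seed = 3)
  for (d in list(c(180, 180), c(999, 868), c(41, 77))) {
    img <- image_plane(matrix(runif(prod(d)), d[1]))
    expect_equal(dim(denoise(m, img)$pixels), d)
  }
})

test_that("denoising is deterministic in eval mode", {
  m <- build_dncnn(dncnn_config(depth = 4, width = 8), seed = 4)
  img <- matrix(runif(32 * 32), 32)
  expect_identical(denoise(m, img)$pixels, denoise(m, img)$pixels)
})

test_that("feature extractor exposes the documented tap geometry", {
  ex1 <- build_feature_extractor("relu1_2", seed = 1)
  fs <- extract_features(ex1, matrix(runif(180 * 180), 180))
  expect_equal(unname(fs$dims$relu1_2), c(180, 180, 64))
  ex <- build_feature_extractor(seed = 1)
  fs5 <- extract_features(ex, matrix(runif(224 * 224), 224))
  depths <- vapply(fs5$dims, function(d) unname(d["d"]), numeric(1))
  sides <- vapply(fs5$dims, function(d) unname(d["h"]), numeric(1))
  expect_equal(unname(depths), c(64, 128, 256, 512, 512))
  expect_equal(unname(sides), c(224, 112, 56, 28, 14))
  expect_error(build_feature_extractor("relu9_9"), "unknown tap")
  expect_error(build_feature_extractor(character(0)), "at least one tap")
})

test_that("identical inputs give identical feature stacks", {
  ex <- build_feature_extractor(c("relu1_2", "relu2_2"), seed = 2)
  img <- matrix(runif(32 * 32), 32)
  a <- extract_features(ex, img)
  b <- extract_features(ex, img)
  expect_identical(a$taps, b$taps)
  for (nm in names(a$taps))
    expect_equal(unname(a$dims[[nm]]),
                 unname(dim(a$taps[[nm]])[c(2, 1, 3)]))
})

test_that("extractor weights are frozen through an optimizer step", {
  ex <- build_feature_extractor(c("relu1_2", "relu2_2"), seed = 5)
  before <- lapply(ex$layers, function(l) l$w)
  ts <- toy_training_set(n_pairs = 1, h = 48, w = 48, patch = 16L,
                         stride = 16L, seed_base = 40L)
  model <- build_dncnn(dncnn_config(depth = 3, width = 4), seed = 1)
  cfg <- train_config(batch_size = 4L, steps = 2L, seed = 1, val_every = 1L)
  tr <- train_dncnn(model, ts$patches,
                    loss_spec(taps = c(relu1_2 = 0.5, relu2_2 = 0.5)),
                    cfg, extractor = ex)
  after <- lapply(ex$layers, function(l) l$w)
  expect_identical(before, after)                 # bitwise unchanged
  # ...while the denoiser itself did change
  expect_false(identical(model$layers[[1]]$w, tr$model$layers[[1]]$w))
})

test_that("feature distances at all taps and shallow taps co-vary", {
  ex <- build_feature_extractor(seed = 6)
  pairs <- lapply(1:16, function(i)
    synthesize_pair(phantom_config(height = 32, width = 32, n_layers = 4,
                                   layer_intensities = c(0.05, 0.5, 0.25, 0.65),
                                   boundary_waviness = 1, foveal_dip = 2,
                                   vessel_shadows = 0, seed = i),
                    speckle_config(looks = 2 + (i %% 4), n_frames = 4,
                                   seed = 900 + i)))
  d_all <- vapply(pairs, function(p)
    feature_distance(ex, p$noisy, p$reference), numeric(1))
  d_123 <- vapply(pairs, function(p)
    feature_distance(ex, p$noisy, p$reference,
                     taps = c("relu1_2", "relu2_2", "relu3_3")), numeric(1))
  expect_gt(cor(d_all, d_123, method = "spearman"), 0)
})

test_that("checkpoints round-trip with their json sidecar", {
  m <- build_dncnn(dncnn_config(depth = 3, width = 4), seed = 7)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, loss_spec = loss_spec(l2 = 1), epoch = 12)
  m2 <- load_checkpoint(path)
  expect_identical(m2$layers, m$layers)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$config$depth, 3)
  expect_equal(side$epoch, 12)
  unlink(c(path, paste0(path, ".json")))
})
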