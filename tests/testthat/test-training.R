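test_that("patch grid counts follow the closed form", {
  mk <- function(h, w) list(noisy = image_plane(matrix(0.5, h, w)),
                            reference = image_plane(matrix(0.5, h, w)))
  prot <- patch_protocol(patch = 180L, stride = 45L)
  expect_equal(dim(extract_patches(mk(180, 180), prot)$noisy)[4], 1L)
  # full-size B-scan geometry: (floor((999-180)/45)+1) * (floor((868-180)/45)+1)
  ps <- extract_patches(mk(999, 868), prot)
  expect_equal(dim(ps$noisy)[4], 19L * 16L)
  expect_equal(dim(ps$noisy)[4], 304L)
  # arbitrary-size property
  for (d in list(c(200, 215), c(181, 300))) {
    n <- dim(extract_patches(mk(d[1], d[2]), prot)$noisy)[4]
    expect_equal(n, (floor((d[1] - 180) / 45) + 1) *
                    (floor((d[2] - 180) / 45) + 1))
  }
  expect_error(patch_protocol(patch = 40, stride = 50), "stride")
})

test_that("noisy and reference patches stay co-located", {
  pair <- synthesize_pair(phantom_config(height = 96, width = 96, seed = 1),
                          speckle_config(seed = 1))
  prot <- patch_protocol(patch = 32L, stride = 32L)
  ps <- extract_patches(pair, prot)
  q <- 5L
  r0 <- ps$corners$row[q]; c0 <- ps$corners$col[q]
  expect_equal(ps$noisy[, , 1, q],
               norm01(pair$noisy)[r0:(r0 + 31), c0:(c0 + 31)])
  expect_equal(ps$reference[, , 1, q],
               norm01(pair$reference)[r0:(r0 + 31), c0:(c0 + 31)])
})

test_that("too-small images yield an empty patch set with a warning", {
  mk <- list(noisy = image_plane(matrix(0.5, 64, 64)),
             reference = image_plane(matrix(0.5, 64, 64)))
  expect_warning(ps <- extract_patches(mk, patch_protocol()), "smaller")
  expect_equal(dim(ps$noisy)[4], 0L)
})

test_that("structure filter drops background patches and is idempotent", {
  # top half empty vitreous, bottom half layered tissue
  pc <- phantom_config(height = 128, width = 64, n_layers = 3,
                       layer_intensities = c(0.02, 0.55, 0.35),
                       boundary_waviness = 0, foveal_dip = 0,
                       vessel_shadows = 0, seed = 2)
  pair <- synthesize_pair(pc, speckle_config(looks = 4, seed = 2))
  prot <- patch_protocol(patch = 16L, stride = 16L)
  ps <- extract_patches(pair, prot)
  f1 <- filter_patches(ps, prot)
  expect_gt(attr(f1, "removed"), 0)                  # vitreous went away
  expect_gt(dim(f1$noisy)[4], 0)                     # tissue retained
  # retained patches overlap the layered region (first boundary ~ row 19)
  expect_true(all(f1$corners$row + 15 >= 19))
  f2 <- filter_patches(f1, prot)
  expect_equal(dim(f2$noisy)[4], dim(f1$noisy)[4])   # idempotent
  # all-background phantom: everything removed -> error
  flat <- list(noisy = image_plane(matrix(0.01, 64, 64)),
               reference = image_plane(matrix(0.01, 64, 64)))
  psf <- extract_patches(flat, prot)
  expect_error(filter_patches(psf, prot), "removed every patch")
})

test_that("a few optimizer steps reduce the training loss deterministically", {
  ts <- toy_training_set(n_pairs = 1, h = 64, w = 64, patch = 16L,
                         stride = 16L, seed_base = 10L)
  model <- build_dncnn(dncnn_config(depth = 3, width = 8), seed = 5)
  cfg <- train_config(batch_size = 8L, steps = 25L, seed = 5, val_every = 5L,
                      monitor_losses = list(mon_l2 = loss_spec(l2 = 1)))
  tr1 <- train_dncnn(model, ts$patches, loss_spec(l2 = 1), cfg)
  tr2 <- train_dncnn(model, ts$patches, loss_spec(l2 = 1), cfg)
  expect_identical(tr1$history, tr2$history)        # seeded determinism
  expect_lt(tail(tr1$history$train_loss, 1), tr1$history$train_loss[1])
  expect_true(all(c("step", "train_loss", "mon_l2") %in%
                    names(tr1$history)))
})

test_that("monitor losses never touch the weights", {
  ts <- toy_training_set(n_pairs = 1, h = 48, w = 48, patch = 16L,
                         stride = 16L, seed_base = 20L)
  model <- build_dncnn(dncnn_config(depth = 3, width = 4), seed = 6)
  base <- train_config(batch_size = 4L, steps = 6L, seed = 6, val_every = 2L)
  with_mon <- base
  with_mon$monitor_losses <- list(l1 = loss_spec(l1 = 1))
  tr_a <- train_dncnn(model, ts$patches, loss_spec(l2 = 1), base)
  tr_b <- train_dncnn(model, ts$patches, loss_spec(l2 = 1), with_mon)
  expect_identical(tr_a$model$layers, tr_b$model$layers)
})

test_that("train_select returns the argmax of validation psnr", {
  ts <- toy_training_set(n_pairs = 1, h = 48, w = 48, patch = 16L,
                         stride = 16L, seed_base = 30L)
  val <- list(synthesize_pair(phantom_config(height = 48, width = 48,
                                             seed = 77),
                              speckle_config(seed = 77)))
  cfg <- train_config(batch_size = 4L, steps = 8L, seed = 3, repeats = 3L,
                      val_every = 4L)
  sel <- train_select(function(s) build_dncnn(dncnn_config(depth = 3,
                                                           width = 4),
                                              seed = s),
                      ts$patches, loss_spec(l2 = 1), cfg, val)
  expect_length(sel$scores, 3L)
  best_psnr <- psnr(denoise(sel$model, val[[1]]$noisy), val[[1]]$reference)
  expect_equal(best_psnr, max(sel$scores))
  # repeats = 1 equals a single train run
  cfg1 <- cfg; cfg1$repeats <- 1L
  sel1 <- train_select(function(s) build_dncnn(dncnn_config(depth = 3,
                                                            width = 4),
                                               seed = s),
                       ts$patches, loss_spec(l2 = 1), cfg1, val)
  single <- train_dncnn(build_dncnn(dncnn_config(depth = 3, width = 4),
                                    seed = cfg$seed),
                        ts$patches, loss_spec(l2 = 1), cfg1, NULL, val)
  expect_identical(sel1$model$layers, single$model$layers)
})

test_that("evaluate_checkpoint reports per-image rows plus their mean", {
  pairs <- lapply(1:2, function(i)
    synthesize_pair(phantom_config(height = 96, width = 96, seed = 50 + i),
                    speckle_config(seed = 50 + i)))
  m <- build_dncnn(dncnn_config(depth = 3, width = 4), seed = 1)
  psip <- psi_params(block_size = 16)
  jnbp <- jnb_params(block_size = 32)
  s3p <- s3_params(s1_block = 32)
  tab <- evaluate_checkpoint(m, pairs, psi = psip, jnbp = jnbp, s3p = s3p)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$image[3], "mean")
  expect_equal(tab$psnr[3], mean(tab$psnr[1:2]))
  expect_true(any(grepl("^epi_", names(tab))))
  # identity model: metrics equal those of the raw noisy images
  id <- m
  id$layers <- lapply(id$layers, function(l) {
    if (l$type == "conv") { l$w[] <- 0; if (!is.null(l$b)) l$b[] <- 0 }
    l
  })
  tab_id <- evaluate_checkpoint(id, pairs, psi = psip, jnbp = jnbp, s3p = s3p)
  direct <- evaluate_sharpness(pairs[[1]]$noisy, pairs[[1]]$reference,
                               pairs[[1]]$boundaries,
                               psi = psip, jnbp = jnbp, s3p = s3p)
  expect_equal(tab_id$psnr[1], direct$psnr)
  expect_equal(tab_id$psi[1], direct$psi)
  expect_equal(tab_id$s3[1], direct$s3)
})
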