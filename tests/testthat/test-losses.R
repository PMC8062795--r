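test_that("pixel losses match direct sums and vanish on identical input", {
  p <- array(runif(8), c(2, 2, 1, 2))
  expect_equal(pixel_loss("l1", p, p), 0)
  expect_equal(pixel_loss("l2", p, p), 0)
  a <- array(0, c(2, 2, 1, 1))
  b <- a; b[2, 2, 1, 1] <- 0.5
  expect_equal(pixel_loss("l2", a, b), 0.25)   # one pixel off by 0.5
  expect_equal(pixel_loss("l1", a, b), 0.5)
  expect_error(pixel_loss("l2", a, array(0, c(3, 3, 1, 1))), "shapes")
})

test_that("pixel l2 is invariant to a joint pixel permutation", {
  set.seed(8)
  a <- array(runif(32), c(4, 4, 1, 2))
  b <- array(runif(32), c(4, 4, 1, 2))
  perm <- sample(16)
  ap <- a; bp <- b
  for (n in 1:2) {
    ap[, , 1, n] <- matrix(as.vector(a[, , 1, n])[perm], 4)
    bp[, , 1, n] <- matrix(as.vector(b[, , 1, n])[perm], 4)
  }
  expect_equal(pixel_loss("l2", a, b), pixel_loss("l2", ap, bp))
})

test_that("identity-extractor feature loss reduces to normalized mse", {
  st <- stub_extractor()
  set.seed(1)
  p <- array(runif(64), c(8, 8, 1, 1))
  y <- array(runif(64), c(8, 8, 1, 1))
  expect_equal(feature_loss(st, "input", p, p), 0)
  # 3 replicated channels, normalized by w*h*d: exactly the pixel MSE
  expect_equal(feature_loss(st, "input", p, y), mean((p - y)^2))
})

test_that("unit channel weights reproduce the unweighted feature loss", {
  ex <- build_feature_extractor("relu1_2", seed = 2)
  set.seed(2)
  p <- array(runif(256), c(16, 16, 1, 1))
  y <- array(runif(256), c(16, 16, 1, 1))
  base <- feature_loss(ex, "relu1_2", p, y)
  expect_equal(feature_loss(ex, "relu1_2", p, y,
                            channel_weights = rep(1, 64)), base)
  halved <- feature_loss(ex, "relu1_2", p, y,
                         channel_weights = rep(0.5, 64))
  expect_equal(halved, base / 2)
  expect_error(feature_loss(ex, "relu1_2", p, y,
                            channel_weights = rep(1, 3)),
               "channel_weights length")
  expect_error(feature_loss(ex, "relu5_3", p, y), "not built")
})

test_that("loss_spec validates its coefficients", {
  expect_error(loss_spec(), "nonzero coefficient")
  expect_error(loss_spec(l2 = -1), ">= 0")
  expect_error(loss_spec(taps = 0.5), "named")
})

test_that("combined loss degenerates to its single terms", {
  ex <- build_feature_extractor(c("relu1_2", "relu2_2"), seed = 3)
  set.seed(3)
  p <- array(runif(256), c(16, 16, 1, 1))
  y <- array(runif(256), c(16, 16, 1, 1))
  only_l2 <- combined_loss(loss_spec(l2 = 1), NULL, p, y)
  expect_equal(only_l2$total, pixel_loss("l2", p, y))
  single <- combined_loss(loss_spec(taps = c(relu1_2 = 1)), ex, p, y)
  expect_equal(single$total, feature_loss(ex, "relu1_2", p, y))
  expect_error(combined_loss(loss_spec(taps = c(relu1_2 = 1)), NULL, p, y),
               "no extractor")
})

test_that("combined loss is linear in its coefficients and decomposable", {
  ex <- build_feature_extractor(c("relu1_2", "relu2_2"), seed = 3)
  set.seed(4)
  p <- array(runif(256), c(16, 16, 1, 1))
  y <- array(runif(256), c(16, 16, 1, 1))
  spec1 <- loss_spec(l1 = 0.2, l2 = 0.5,
                     taps = c(relu1_2 = 0.3, relu2_2 = 0.7))
  spec2 <- loss_spec(l1 = 0.4, l2 = 1.0,
                     taps = c(relu1_2 = 0.6, relu2_2 = 1.4))
  r1 <- combined_loss(spec1, ex, p, y)
  r2 <- combined_loss(spec2, ex, p, y)
  expect_equal(r2$total, 2 * r1$total)
  expect_equal(sum(r1$breakdown), r1$total)
  expect_named(r1$breakdown, c("l1", "l2", "relu1_2", "relu2_2"))
  expect_true(all(r1$breakdown >= 0))
})

test_that("loss gradients are nonzero for distinct inputs and match fd", {
  ex <- build_feature_extractor("relu1_2", seed = 5)
  spec <- loss_spec(l1 = 0.3, l2 = 0.5, taps = c(relu1_2 = 0.4))
  set.seed(5)
  p <- array(runif(128), c(8, 8, 1, 2))
  y <- array(runif(128), c(8, 8, 1, 2))
  g <- octsharp:::combined_loss_grad(spec, ex, p, y)
  expect_gt(max(abs(g)), 0)
  eps <- 1e-5
  for (t in c(3, 64, 100)) {
    pp <- p; pp[t] <- pp[t] + eps
    pm <- p; pm[t] <- pm[t] - eps
    fd <- (combined_loss(spec, ex, pp, y)$total -
             combined_loss(spec, ex, pm, y)$total) / (2 * eps)
    expect_equal(g[t], fd, tolerance = 1e-4)
  }
})
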