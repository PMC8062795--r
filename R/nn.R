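#' @useDynLib octsharp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft quantile rnorm runif sd var cor
#' @importFrom utils read.csv write.csv
NULL

# ------------------------------------------------------------------
# Minimal convolutional-network engine.
#
# Activations are 4-d arrays [H, W, C, N]; conv weights [k, k, Cin, Cout].
# A network is a plain list of layer lists; forward returns per-layer caches
# so the backward pass can produce both input gradients (needed to drive a
# denoiser through a frozen feature extractor) and parameter gradients.
# ------------------------------------------------------------------

layer_conv <- function(in_ch, out_ch, k = 3L, bias = TRUE) {
  list(type = "conv", in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       k = as.integer(k),
       w = array(0, c(k, k, in_ch, out_ch)),
       b = if (bias) numeric(out_ch) else NULL)
}

layer_bn <- function(ch, eps = 1e-5, momentum = 0.9) {
  list(type = "bn", ch = as.integer(ch), eps = eps, momentum = momentum,
       gamma = rep(1, ch), beta = numeric(ch),
       rmean = numeric(ch), rvar = rep(1, ch))
}

layer_relu <- function() list(type = "relu")
layer_maxpool <- function() list(type = "maxpool")

# He-uniform fan-in initialization, in place, consuming the R RNG stream.
init_conv <- function(layer) {
  fan_in <- layer$k^2 * layer$in_ch
  lim <- sqrt(6 / fan_in)
  layer$w[] <- runif(length(layer$w), -lim, lim)
  if (!is.null(layer$b)) layer$b[] <- 0
  layer
}

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$type == "conv") {
      caches[[l]] <- list(x = x)
      x <- conv2d_fwd(x, ly$w, ly$b)
    } else if (ly$type == "relu") {
      caches[[l]] <- list(pos = x > 0)
      x <- x * caches[[l]]$pos
    } else if (ly$type == "bn") {
      d <- dim(x); m <- d[1] * d[2] * d[4]
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), nrow = m)   # m x C
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        layers[[l]]$rmean <- ly$momentum * ly$rmean + (1 - ly$momentum) * mu
        layers[[l]]$rvar  <- ly$momentum * ly$rvar  + (1 - ly$momentum) * v
      } else {
        mu <- ly$rmean; v <- ly$rvar
      }
      istd <- 1 / sqrt(v + ly$eps)
      xhat <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
      ym <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      caches[[l]] <- list(xhat = xhat, istd = istd, d = d, train = train)
      x <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    } else if (ly$type == "maxpool") {
      r <- maxpool2_fwd(x)
      caches[[l]] <- list(idx = r$idx, xdim = dim(x))
      x <- r$y
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = x, caches = caches, layers = layers)
}

# dout: gradient at the network output.  tap_grads: optional list mapping
# layer index -> gradient to inject into the flow at that layer's output
# (used for multi-tap feature losses).  Set param_grads = FALSE for frozen
# networks: only dx is computed, weight gradients are skipped.
nn_backward <- function(layers, caches, dout, tap_grads = NULL,
                        param_grads = TRUE) {
  grads <- if (param_grads) vector("list", length(layers)) else NULL
  for (l in rev(seq_along(layers))) {
    if (!is.null(tap_grads) && !is.null(tap_grads[[as.character(l)]])) {
      tg <- tap_grads[[as.character(l)]]
      dout <- if (is.null(dout)) tg else dout + tg
    }
    if (is.null(dout)) next
    ly <- layers[[l]]; ca <- caches[[l]]
    if (ly$type == "conv") {
      r <- conv2d_bwd(ca$x, ly$w, dout, param_grads)
      if (param_grads) grads[[l]] <- list(w = r$dw, b = r$db)
      dout <- r$dx
    } else if (ly$type == "relu") {
      dout <- dout * ca$pos
    } else if (ly$type == "bn") {
      d <- ca$d; m <- d[1] * d[2] * d[4]
      dm <- matrix(aperm(dout, c(1, 2, 4, 3)), nrow = m)
      if (param_grads)
        grads[[l]] <- list(gamma = colSums(dm * ca$xhat), beta = colSums(dm))
      dxhat <- sweep(dm, 2, ly$gamma, "*")
      if (ca$train) {
        s1 <- colSums(dxhat); s2 <- colSums(dxhat * ca$xhat)
        dxm <- sweep(dxhat * m, 2, s1, "-") - sweep(ca$xhat, 2, s2, "*")
        dxm <- sweep(dxm, 2, ca$istd / m, "*")
      } else {
        dxm <- sweep(dxhat, 2, ca$istd, "*")
      }
      dout <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    } else if (ly$type == "maxpool") {
      dout <- maxpool2_bwd(ca$idx, dout, ca$xdim)
    }
  }
  list(dx = dout, grads = grads)
}

# ---- trainable-parameter bookkeeping ------------------------------------

param_fields <- function(type)
  switch(type, conv = c("w", "b"), bn = c("gamma", "beta"), character(0))

#' Number of trainable parameters in a network
#'
#' Counts convolution weights and biases plus the two learned
#' batch-normalization terms (scale and shift) per channel; running
#' statistics are not trainable and are not counted.
#'
#' @param model a denoiser or feature extractor built by this package
#' @return integer count
#' @export
n_parameters <- function(model) {
  layers <- model$layers
  sum(vapply(layers, function(ly) {
    sum(vapply(param_fields(ly$type), function(f)
      length(ly[[f]]), numeric(1)))
  }, numeric(1)))
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    fs <- param_fields(ly$type)
    fs <- fs[vapply(fs, function(f) !is.null(ly[[f]]), logical(1))]
    st <- lapply(fs, function(f)
      list(m = ly[[f]] * 0, v = ly[[f]] * 0))
    names(st) <- fs
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    if (is.null(g)) next
    for (f in names(state[[l]])) {
      gf <- g[[if (f == "w") "w" else if (f == "b") "b" else f]]
      if (is.null(gf)) next
      st <- state[[l]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * gf
      st$v <- beta2 * st$v + (1 - beta2) * gf^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[l]][[f]] <- layers[[l]][[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[f]] <- st
    }
  }
  list(layers = layers, state = state)
}
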