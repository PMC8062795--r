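# ------------------------------------------------------------------
# Loss algebra: pixelwise L1/L2 terms, per-tap deep-feature terms with
# optional per-channel (LPIPS-style) weights, and their weighted sum.
# Pixel losses are per-batch means of per-image *summed* norms; feature
# losses additionally carry the 1/(w*h*d) tap normalization.
# ------------------------------------------------------------------

#' Declarative loss specification
#'
#' @param l1,l2 coefficients of the pixelwise L1 and L2 terms (>= 0)
#' @param taps named numeric vector of per-tap feature-loss weights
#'   (the scalar weighting factors of the combined relu-VGG loss), e.g.
#'   `c(relu1_2 = 0.2, ..., relu5_3 = 0.2)`; empty for pixel-only losses.
#'   The all-tap default uses equal weights 1/5.
#' @param channel_weights optional named list (per tap) of per-channel
#'   weight vectors applied to the squared feature differences
#'   (LPIPS-style calibrated weights, loadable from a user file)
#' @return a `loss_spec` object
#' @export
loss_spec <- function(l1 = 0, l2 = 0, taps = numeric(0),
                      channel_weights = NULL) {
  if (l1 < 0 || l2 < 0 || any(taps < 0))
    stop("loss coefficients must be >= 0")
  if (l1 + l2 + sum(taps) == 0)
    stop("loss must have at least one nonzero coefficient")
  if (length(taps) && is.null(names(taps)))
    stop("taps must be a named vector")
  structure(list(l1 = l1, l2 = l2, taps = taps,
                 channel_weights = channel_weights),
            class = "loss_spec")
}

#' All-tap feature loss with equal weights
#' @param weight total feature weight, split equally over the five taps
#' @return a `loss_spec`
#' @export
vgg_loss_spec <- function(weight = 1) {
  w <- rep(weight / 5, 5)
  names(w) <- VGG_TAPS
  loss_spec(taps = w)
}

#' Pixelwise loss
#'
#' `(1/n) * sum_i ||pred_i - target_i||` with the L2 norm squared or the
#' L1 norm, `n` the batch size; per-image norms are sums over pixels.
#'
#' @param kind `"l1"` or `"l2"`
#' @param predicted,target `[H,W,C,N]` arrays (or matrices) of equal shape
#' @return non-negative scalar
#' @export
pixel_loss <- function(kind = c("l2", "l1"), predicted, target) {
  kind <- match.arg(kind)
  predicted <- as_batch(predicted); target <- as_batch(target)
  if (!identical(dim(predicted), dim(target)))
    stop("predicted and target shapes differ")
  n <- dim(predicted)[4]
  d <- predicted - target
  if (kind == "l2") sum(d^2) / n else sum(abs(d)) / n
}

# gradient of pixel_loss w.r.t. predicted
pixel_loss_grad <- function(kind, predicted, target) {
  n <- dim(predicted)[4]
  d <- predicted - target
  if (kind == "l2") 2 * d / n else sign(d) / n
}

#' Deep-feature loss at one tap
#'
#' `(1/n) * (1/(w*h*d)) * sum_i ||phi(pred_i) - phi(target_i)||^2` at the
#' given tap of a frozen extractor. With `channel_weights`, channel `c`'s
#' squared differences are scaled by its weight before summation.
#'
#' @param extractor a [build_feature_extractor()] or [stub_extractor()]
#' @param tap tap name exposed by the extractor
#' @param predicted,target `[H,W,1,N]` batches on the `[0, 1]` scale
#' @param channel_weights optional per-channel weight vector (length = tap
#'   depth)
#' @return non-negative scalar
#' @export
feature_loss <- function(extractor, tap, predicted, target,
                         channel_weights = NULL) {
  if (!tap %in% names(extractor$taps))
    stop("tap '", tap, "' not built in this extractor")
  predicted <- as_batch(predicted); target <- as_batch(target)
  fp <- extractor_forward(extractor, predicted)$taps[[tap]]
  ft <- extractor_forward(extractor, target)$taps[[tap]]
  tap_sq_err(fp, ft, channel_weights)
}

tap_sq_err <- function(fp, ft, channel_weights = NULL) {
  d <- dim(fp)
  whd <- d[1] * d[2] * d[3]
  n <- d[4]
  sq <- (fp - ft)^2
  if (!is.null(channel_weights)) {
    if (length(channel_weights) != d[3])
      stop("channel_weights length must equal tap depth")
    for (c_ in seq_len(d[3]))
      sq[, , c_, ] <- sq[, , c_, ] * channel_weights[c_]
  }
  sum(sq) / (n * whd)
}

# gradient of tap_sq_err w.r.t. fp
tap_sq_err_grad <- function(fp, ft, channel_weights = NULL) {
  d <- dim(fp)
  g <- 2 * (fp - ft) / (d[4] * d[1] * d[2] * d[3])
  if (!is.null(channel_weights))
    for (c_ in seq_len(d[3]))
      g[, , c_, ] <- g[, , c_, ] * channel_weights[c_]
  g
}

#' Combined loss
#'
#' Weighted sum of the pixel terms and the per-tap feature terms of a
#' [loss_spec()], with a per-term breakdown for monitoring.
#'
#' @param spec a [loss_spec()]
#' @param extractor feature extractor; required iff any tap weight is
#'   nonzero
#' @param predicted,target `[H,W,1,N]` batches
#' @return list with `total` and named `breakdown` (already weighted)
#' @export
combined_loss <- function(spec, extractor = NULL, predicted, target) {
  predicted <- as_batch(predicted); target <- as_batch(target)
  br <- numeric(0)
  if (spec$l1 > 0)
    br["l1"] <- spec$l1 * pixel_loss("l1", predicted, target)
  if (spec$l2 > 0)
    br["l2"] <- spec$l2 * pixel_loss("l2", predicted, target)
  active <- spec$taps[spec$taps > 0]
  if (length(active)) {
    if (is.null(extractor))
      stop("feature terms requested but no extractor supplied")
    fp <- extractor_forward(extractor, predicted)$taps
    ft <- extractor_forward(extractor, target)$taps
    for (nm in names(active)) {
      if (!nm %in% names(extractor$taps))
        stop("tap '", nm, "' not built in this extractor")
      br[nm] <- active[[nm]] *
        tap_sq_err(fp[[nm]], ft[[nm]], spec$channel_weights[[nm]])
    }
  }
  list(total = sum(br), breakdown = br)
}

# gradient of the combined loss w.r.t. the predicted batch.  Feature-term
# gradients are injected at the tap layers and backpropagated through the
# frozen extractor (input gradient only; extractor weights untouched).
combined_loss_grad <- function(spec, extractor, predicted, target) {
  g <- array(0, dim(predicted))
  if (spec$l1 > 0)
    g <- g + spec$l1 * pixel_loss_grad("l1", predicted, target)
  if (spec$l2 > 0)
    g <- g + spec$l2 * pixel_loss_grad("l2", predicted, target)
  active <- spec$taps[spec$taps > 0]
  if (length(active)) {
    fw <- extractor_forward(extractor, predicted, keep_caches = TRUE)
    ft <- extractor_forward(extractor, target)$taps
    tap_grads <- list()
    g_input0 <- NULL  # gradient arriving at the preprocessed input directly
    for (nm in names(active)) {
      tg <- active[[nm]] * tap_sq_err_grad(fw$taps[[nm]], ft[[nm]],
                                           spec$channel_weights[[nm]])
      li <- extractor$taps[[nm]]
      if (li == 0L) {
        g_input0 <- if (is.null(g_input0)) tg else g_input0 + tg
      } else {
        key <- as.character(li)
        tap_grads[[key]] <- if (is.null(tap_grads[[key]]))
          tg else tap_grads[[key]] + tg
      }
    }
    dxin <- NULL
    if (length(tap_grads)) {
      deepest <- max(extractor$taps)
      bw <- nn_backward(extractor$layers[seq_len(deepest)],
                        fw$caches, NULL, tap_grads, param_grads = FALSE)
      dxin <- bw$dx
    }
    if (!is.null(g_input0))
      dxin <- if (is.null(dxin)) g_input0 else dxin + g_input0
    g <- g + vgg_preprocess_bwd(dxin, extractor$preprocess)
  }
  g
}
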