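# ------------------------------------------------------------------
# Patch-based training protocol: overlapping patch extraction, structure
# filtering, Adam optimization with dual-loss monitoring, and
# repeat-and-select model selection by validation PSNR.
# ------------------------------------------------------------------

#' Patch extraction protocol
#'
#' @param patch patch side in pixels (default 180)
#' @param stride grid stride in pixels (default 45); `0 < stride <= patch`
#' @param std_threshold structure filter: minimum reference-patch
#'   intensity standard deviation on the `[0, 1]` scale (default 0.02)
#' @param min_foreground_fraction structure filter: minimum fraction of
#'   patch pixels above twice the background level (default 0.05)
#' @return a `patch_protocol` list
#' @export
patch_protocol <- function(patch = 180L, stride = 45L,
                           std_threshold = 0.02,
                           min_foreground_fraction = 0.05) {
  if (stride <= 0 || stride > patch)
    stop("need 0 < stride <= patch")
  structure(list(patch = as.integer(patch), stride = as.integer(stride),
                 std_threshold = std_threshold,
                 min_foreground_fraction = min_foreground_fraction),
            class = "patch_protocol")
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001)
#' @param batch_size mini-batch size (default 128)
#' @param steps number of optimization steps
#' @param seed master seed for shuffling and initialization
#' @param repeats training repetitions for repeat-and-select (default 5)
#' @param val_every validation / monitoring cadence in steps
#' @param monitor_losses named list of [loss_spec()]s evaluated (never
#'   optimized) at each validation pass, enabling pixel-vs-feature loss
#'   convergence comparisons
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128L,
                         steps = 100L, seed = 1L, repeats = 5L,
                         val_every = 20L, monitor_losses = list()) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), seed = as.integer(seed),
                 repeats = as.integer(repeats),
                 val_every = as.integer(val_every),
                 monitor_losses = monitor_losses),
            class = "train_config")
}

#' Extract co-located patches from an image pair
#'
#' Lays a grid of top-left corners at multiples of `stride` such that each
#' patch lies fully inside the image, and cuts the same grid from the
#' noisy and reference images (and the clean image when present).
#'
#' @param pair an `image_pair` (see [synthesize_pair()]) or a list with
#'   `noisy` and `reference` image planes
#' @param protocol a [patch_protocol()]
#' @return a `patch_set`: list with `noisy`, `reference` (and `clean`)
#'   `[p,p,1,N]` arrays and a `corners` data.frame; empty (with a warning)
#'   when the image is smaller than the patch
#' @export
extract_patches <- function(pair, protocol = patch_protocol()) {
  p <- protocol$patch; s <- protocol$stride
  nz <- norm01(pair$noisy); rf <- norm01(pair$reference)
  cl <- if (!is.null(pair$clean)) norm01(pair$clean)
  h <- nrow(nz); w <- ncol(nz)
  if (h < p || w < p) {
    warning("image smaller than patch; empty patch set")
    return(structure(list(noisy = array(0, c(p, p, 1, 0)),
                          reference = array(0, c(p, p, 1, 0)),
                          corners = data.frame(row = integer(0),
                                               col = integer(0))),
                     class = "patch_set"))
  }
  rs <- seq(1L, h - p + 1L, by = s)
  cs <- seq(1L, w - p + 1L, by = s)
  corners <- expand.grid(row = rs, col = cs)
  n <- nrow(corners)
  cut <- function(m) {
    a <- array(0, c(p, p, 1L, n))
    for (q in seq_len(n))
      a[, , 1, q] <- m[corners$row[q]:(corners$row[q] + p - 1),
                       corners$col[q]:(corners$col[q] + p - 1)]
    a
  }
  out <- list(noisy = cut(nz), reference = cut(rf), corners = corners)
  if (!is.null(cl)) out$clean <- cut(cl)
  structure(out, class = "patch_set")
}

#' Filter patches without retinal structure
#'
#' Keeps a patch iff its reference patch has intensity standard deviation
#' at least `std_threshold` and at least `min_foreground_fraction` of its
#' pixels above twice the background level. The background level is
#' estimated once per patch set as the mean of the darkest 20% of
#' reference pixels and recorded in the `background_level` attribute;
#' re-filtering reuses it, so filtering is idempotent. Removal counts are
#' attached as the `removed` attribute.
#'
#' @param patches a `patch_set` from [extract_patches()]
#' @param protocol a [patch_protocol()]
#' @return filtered `patch_set`
#' @export
filter_patches <- function(patches, protocol = patch_protocol()) {
  n <- dim(patches$reference)[4]
  if (n == 0) return(patches)
  ref <- patches$reference
  bg <- attr(patches, "background_level")     # darkest-quintile background,
  if (is.null(bg))                            # estimated before any removal
    bg <- mean(ref[ref <= quantile(ref, 0.2)])
  keep <- logical(n)
  for (q in seq_len(n)) {
    pr <- ref[, , 1, q]
    keep[q] <- sd(pr) >= protocol$std_threshold &&
      mean(pr > 2 * bg) >= protocol$min_foreground_fraction
  }
  if (!any(keep))
    stop("structure filter removed every patch; training impossible")
  out <- patches
  for (f in c("noisy", "reference", "clean"))
    if (!is.null(out[[f]])) out[[f]] <- out[[f]][, , , keep, drop = FALSE]
  out$corners <- patches$corners[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  attr(out, "background_level") <- bg
  out
}

#' Train a denoiser
#'
#' Adam optimization of the residual network on shuffled mini-batches.
#' The optimized loss is evaluated on each batch; at every `val_every`
#' steps the current model is additionally scored, with gradients
#' disabled, under every monitor loss (and by validation PSNR when
#' validation pairs are given). The run is deterministic for a fixed
#' seed in single-threaded mode.
#'
#' @param model a [build_dncnn()] model
#' @param patches a non-empty `patch_set`
#' @param spec the optimized [loss_spec()]
#' @param cfg a [train_config()]
#' @param extractor feature extractor, required iff `spec` (or a monitor
#'   loss) has feature terms
#' @param validation optional list of image pairs for validation PSNR
#' @return list with `model` (trained), `history` (data.frame: step,
#'   train_loss, monitor columns, val_psnr)
#' @export
train_dncnn <- function(model, patches, spec, cfg, extractor = NULL,
                        validation = NULL) {
  n <- dim(patches$noisy)[4]
  if (n == 0) stop("empty patch set")
  layers <- model$layers    # force the model before seeding the shuffle:
  state <- adam_init(layers)  # building it may consume the RNG
  set.seed(cfg$seed)
  hist <- list()
  order <- sample.int(n)
  pos <- 1L
  bs <- min(cfg$batch_size, n)
  for (step in seq_len(cfg$steps)) {
    if (pos + bs - 1L > n) { order <- sample.int(n); pos <- 1L }
    idx <- order[pos:(pos + bs - 1L)]
    pos <- pos + bs
    x <- patches$noisy[, , , idx, drop = FALSE]
    y <- patches$reference[, , , idx, drop = FALSE]
    model$layers <- layers
    fw <- dncnn_residual(model, x, train = TRUE)
    layers <- fw$layers                      # BN running stats updated
    pred <- x - fw$out
    lval <- combined_loss(spec, extractor, pred, y)$total
    if (!is.finite(lval))
      stop("non-finite training loss at step ", step,
           " (learning rate too high or degenerate batch)")
    dpred <- combined_loss_grad(spec, extractor, pred, y)
    dres <- -dpred                           # pred = x - residual
    bw <- nn_backward(layers, fw$caches, dres, param_grads = TRUE)
    up <- adam_step(layers, bw$grads, state, cfg$learning_rate, step)
    layers <- up$layers; state <- up$state
    if (step %% cfg$val_every == 0L || step == cfg$steps || step == 1L) {
      model$layers <- layers
      row <- list(step = step, train_loss = lval)
      for (nm in names(cfg$monitor_losses)) {
        ms <- cfg$monitor_losses[[nm]]
        pred_eval <- x - dncnn_residual(model, x, train = FALSE)$out
        row[[nm]] <- combined_loss(ms, extractor, pred_eval, y)$total
      }
      if (!is.null(validation)) {
        ps <- vapply(validation, function(vp) {
          den <- denoise(model, vp$noisy)
          psnr(den, vp$reference)
        }, numeric(1))
        row$val_psnr <- mean(ps)
      }
      hist[[length(hist) + 1L]] <- row
    }
  }
  model$layers <- layers
  history <- do.call(rbind, lapply(hist, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(model = model, history = history)
}

#' Repeat-and-select training
#'
#' Trains `cfg$repeats` models from distinct derived seeds and keeps the
#' one with the highest mean validation PSNR, mirroring the
#' train-five-times-keep-the-best protocol. All candidate scores are
#' returned.
#'
#' @param factory function(seed) returning a fresh untrained model
#' @param patches training `patch_set`
#' @param spec optimized [loss_spec()]
#' @param cfg a [train_config()]
#' @param validation list of image pairs scored by PSNR
#' @param extractor optional feature extractor
#' @return list with `model` (best), `scores` (per-repeat validation
#'   PSNR), `histories`
#' @export
train_select <- function(factory, patches, spec, cfg, validation,
                         extractor = NULL) {
  scores <- numeric(cfg$repeats)
  best <- NULL; histories <- vector("list", cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    seed_r <- (cfg$seed + 1000L * (r - 1L)) %% .Machine$integer.max
    cfg_r <- cfg; cfg_r$seed <- seed_r
    m <- factory(seed_r)
    tr <- train_dncnn(m, patches, spec, cfg_r, extractor, validation)
    ps <- vapply(validation, function(vp)
      psnr(denoise(tr$model, vp$noisy), vp$reference), numeric(1))
    scores[r] <- mean(ps)
    histories[[r]] <- tr$history
    if (r == 1L || scores[r] > max(scores[seq_len(r - 1L)]))
      best <- tr$model
  }
  list(model = best, scores = scores, histories = histories)
}

#' Evaluate a checkpoint on test pairs
#'
#' Denoises every test pair's noisy image whole (no cropping) and
#' assembles the sharpness report table with a mean row.
#'
#' @param model a trained `dncnn` (or checkpoint path)
#' @param pairs list of image pairs (`noisy`, `reference`, optional
#'   `boundaries`, optional `clean`)
#' @param psi,jnbp,s3p metric parameter objects
#' @param reference_field which field PSNR is computed against
#'   (`"reference"` or `"clean"`)
#' @return data.frame, one row per image plus a `"mean"` row
#' @export
evaluate_checkpoint <- function(model, pairs, psi = psi_params(),
                                jnbp = jnb_params(), s3p = s3_params(),
                                reference_field = "reference") {
  if (is.character(model)) model <- load_checkpoint(model)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    den <- denoise(model, p$noisy)
    rep_ <- evaluate_sharpness(den, reference = p[[reference_field]],
                               boundaries = p$boundaries,
                               psi = psi, jnbp = jnbp, s3p = s3p)
    cbind(data.frame(image = as.character(i)), report_row(rep_))
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab[, -1, drop = FALSE], mean, numeric(1))
  tab <- rbind(tab, cbind(data.frame(image = "mean"),
                          as.data.frame(as.list(num))))
  rownames(tab) <- NULL
  tab
}
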