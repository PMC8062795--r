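# ------------------------------------------------------------------
# Tap-able VGG-16 feature extractor.  Only the convolutional trunk is
# built, truncated at the deepest requested tap; the weights are frozen
# and are never touched by any training step.  Grayscale inputs are
# scaled to [0, 255], replicated to three channels and mean-centered
# with the standard ImageNet channel means before the first convolution.
# ------------------------------------------------------------------

VGG_TAPS <- c("relu1_2", "relu2_2", "relu3_3", "relu4_3", "relu5_3")
VGG_BLOCKS <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                   c(512, 512, 512), c(512, 512, 512))
IMAGENET_MEANS <- c(123.68, 116.779, 103.939)

#' Build a frozen VGG-16 feature extractor
#'
#' Constructs the VGG-16 convolutional topology (3x3 convolutions + ReLU
#' in five blocks of widths 64/128/256/512/512, 2x2 max-pooling between
#' blocks) up to the deepest requested tap. Taps are read post-activation
#' at the standard positions (the 2nd, 4th, 7th, 10th and 13th
#' convolutions). Weights come from a user-supplied file when given,
#' otherwise from seeded random initialization (a test-mode extractor);
#' either way they are frozen.
#'
#' @param taps character vector, non-empty subset of
#'   `c("relu1_2", "relu2_2", "relu3_3", "relu4_3", "relu5_3")`
#' @param weights path to an RDS file holding a list of `w`/`b` arrays per
#'   convolution (in trunk order), or `NULL` for random initialization
#' @param seed seed for random initialization
#' @return a `feature_extractor` object
#' @export
build_feature_extractor <- function(taps = VGG_TAPS, weights = NULL,
                                    seed = 1L) {
  if (length(taps) == 0) stop("at least one tap required")
  bad <- setdiff(taps, VGG_TAPS)
  if (length(bad)) stop("unknown tap name(s): ", paste(bad, collapse = ", "))
  taps <- VGG_TAPS[VGG_TAPS %in% taps]  # canonical order
  deepest <- max(match(taps, VGG_TAPS))
  set.seed(seed)
  layers <- list()
  tap_at <- integer(0)       # layer index of each built tap
  in_ch <- 3L
  conv_params <- NULL
  if (!is.null(weights)) {
    conv_params <- readRDS(weights)
    if (!is.list(conv_params)) stop("malformed weights file: ", weights)
  }
  ci <- 0L
  for (blk in seq_len(deepest)) {
    widths <- VGG_BLOCKS[[blk]]
    for (ly in seq_along(widths)) {
      ci <- ci + 1L
      cv <- layer_conv(in_ch, widths[ly], 3L)
      if (!is.null(conv_params)) {
        p <- conv_params[[ci]]
        if (is.null(p$w) || !identical(dim(p$w), dim(cv$w)))
          stop("malformed weights file: conv ", ci, " has wrong shape")
        cv$w <- p$w
        if (!is.null(p$b)) cv$b <- as.numeric(p$b)
      } else {
        cv <- init_conv(cv)
      }
      layers <- c(layers, list(cv, layer_relu()))
      in_ch <- widths[ly]
    }
    tap_at <- c(tap_at, length(layers))        # after the block's last relu
    if (blk < deepest) layers <- c(layers, list(layer_maxpool()))
  }
  tap_idx <- tap_at[match(taps, VGG_TAPS[seq_len(deepest)])]
  names(tap_idx) <- taps
  structure(list(layers = layers, taps = tap_idx,
                 preprocess = "vgg", frozen = TRUE),
            class = "feature_extractor")
}

#' Identity stub extractor
#'
#' A degenerate extractor whose single tap is the raw 3-channel replicated
#' image with no preprocessing; used for diagnostics, where the feature
#' loss must reduce exactly to the normalized pixelwise squared error.
#'
#' @return a `feature_extractor` with one tap named `"input"`
#' @export
stub_extractor <- function() {
  structure(list(layers = list(), taps = c(input = 0L),
                 preprocess = "none", frozen = TRUE),
            class = "feature_extractor")
}

# grayscale [H,W,1,N] on [0,1] -> preprocessed 3-channel tensor
vgg_preprocess <- function(x, mode) {
  d <- dim(x)
  y <- array(0, c(d[1], d[2], 3L, d[4]))
  for (c_ in 1:3) {
    y[, , c_, ] <- if (mode == "vgg")
      x[, , 1, ] * 255 - IMAGENET_MEANS[c_] else x[, , 1, ]
  }
  y
}

# gradient of preprocessing: collapse 3 channels back to grayscale
vgg_preprocess_bwd <- function(dy, mode) {
  d <- dim(dy)
  g <- dy[, , 1, , drop = FALSE] + dy[, , 2, , drop = FALSE] +
    dy[, , 3, , drop = FALSE]
  if (mode == "vgg") g <- g * 255
  g
}

# forward a [H,W,1,N] batch, returning tap activations (+caches if asked)
extractor_forward <- function(extractor, x, keep_caches = FALSE) {
  xin <- vgg_preprocess(x, extractor$preprocess)
  taps_out <- list()
  caches <- NULL
  if (any(extractor$taps == 0L))
    taps_out[[names(extractor$taps)[extractor$taps == 0L]]] <- xin
  taps_idx <- extractor$taps[extractor$taps > 0L]
  if (length(taps_idx)) {
    acts <- forward_with_taps(extractor$layers, xin, taps_idx)
    for (nm in names(taps_idx)) taps_out[[nm]] <- acts$taps[[nm]]
    caches <- acts$caches
  }
  list(taps = taps_out, caches = if (keep_caches) caches else NULL,
       xdim = dim(x))
}

forward_with_taps <- function(layers, x, taps_idx) {
  deepest <- max(taps_idx)
  caches <- vector("list", deepest)
  taps <- list()
  for (l in seq_len(deepest)) {
    ly <- layers[[l]]
    if (ly$type == "conv") {
      caches[[l]] <- list(x = x)
      x <- conv2d_fwd(x, ly$w, ly$b)
    } else if (ly$type == "relu") {
      caches[[l]] <- list(pos = x > 0)
      x <- x * caches[[l]]$pos
    } else if (ly$type == "maxpool") {
      r <- maxpool2_fwd(x)
      caches[[l]] <- list(idx = r$idx, xdim = dim(x))
      x <- r$y
    } else stop("unexpected layer in extractor: ", ly$type)
    if (l %in% taps_idx)
      taps[[names(taps_idx)[match(l, taps_idx)]]] <- x
  }
  list(taps = taps, caches = caches)
}

#' Extract deep features from a grayscale image
#'
#' Rescales the image to the extractor's expected range, replicates it to
#' three channels, mean-centers, forwards it through the frozen trunk and
#' returns the requested tap activations with their (width, height, depth)
#' metadata.
#'
#' @param extractor a [build_feature_extractor()] object
#' @param image an [image_plane()] or matrix (single channel)
#' @return a `feature_stack`: list with `taps` (named list of `[H,W,C,1]`
#'   arrays) and `dims` (named list of `c(w, h, d)`)
#' @export
extract_features <- function(extractor, image) {
  img <- as_image_plane(image)
  blocks <- match(names(extractor$taps), VGG_TAPS)
  deepest_block <- if (all(is.na(blocks))) 1L else max(blocks, na.rm = TRUE)
  min_side <- 2^(deepest_block - 1)
  if (any(dim(img$pixels) < min_side))
    stop("image too small for the deepest requested tap")
  x <- array(norm01(img), c(dim(img$pixels), 1L, 1L))
  fw <- extractor_forward(extractor, x)
  dims <- lapply(fw$taps, function(t_) {
    d <- dim(t_); c(w = d[2], h = d[1], d = d[3])
  })
  structure(list(taps = fw$taps, dims = dims), class = "feature_stack")
}

#' Feature distance between two images
#'
#' Mean over the given taps of the width-height-depth-normalized squared
#' feature difference (the per-tap terms weighted equally).
#'
#' @param extractor a feature extractor
#' @param a,b images of identical size
#' @param taps taps to use (default: all taps of the extractor)
#' @return non-negative scalar distance
#' @export
feature_distance <- function(extractor, a, b,
                             taps = names(extractor$taps)) {
  fa <- extract_features(extractor, a)
  fb <- extract_features(extractor, b)
  vals <- vapply(taps, function(nm) {
    d <- prod(dim(fa$taps[[nm]]))
    sum((fa$taps[[nm]] - fb$taps[[nm]])^2) / d
  }, numeric(1))
  mean(vals)
}
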