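# ------------------------------------------------------------------
# DnCNN residual denoiser: the network predicts the speckle residual and
# the clean estimate is input minus prediction.
# ------------------------------------------------------------------

#' DnCNN configuration
#'
#' @param depth number of convolutional layers (>= 3, default 17)
#' @param width filters per hidden layer (default 64)
#' @param kernel spatial kernel size (default 3); stride is always 1 with
#'   "same" padding so the output matches the input size
#' @return a `dncnn_config` list
#' @export
dncnn_config <- function(depth = 17L, width = 64L, kernel = 3L) {
  if (depth < 3L) stop("depth must be >= 3")
  if (kernel %% 2L != 1L) stop("kernel must be odd")
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 kernel = as.integer(kernel)),
            class = "dncnn_config")
}

#' Build a DnCNN residual denoiser
#'
#' Layer roster: Conv+ReLU in, (depth - 2) x Conv+BatchNorm+ReLU hidden,
#' and a final Conv with a single filter producing the residual map.
#' Weights use seeded He-uniform initialization, so building twice with
#' the same seed gives identical networks.
#'
#' @param config a [dncnn_config()]
#' @param seed integer seed for the initialization
#' @return a `dncnn` model object
#' @export
build_dncnn <- function(config = dncnn_config(), seed = 1L) {
  set.seed(seed)
  k <- config$kernel; wd <- config$width
  layers <- list(layer_conv(1L, wd, k), layer_relu())
  for (i in seq_len(config$depth - 2L)) {
    layers <- c(layers, list(layer_conv(wd, wd, k), layer_bn(wd),
                             layer_relu()))
  }
  layers <- c(layers, list(layer_conv(wd, 1L, k)))
  layers <- lapply(layers, function(ly)
    if (ly$type == "conv") init_conv(ly) else ly)
  structure(list(layers = layers, config = config, seed = as.integer(seed)),
            class = "dncnn")
}

#' @export
print.dncnn <- function(x, ...) {
  cat(sprintf("<dncnn: depth %d, width %d, kernel %d, %d parameters>\n",
              x$config$depth, x$config$width, x$config$kernel,
              n_parameters(x)))
  invisible(x)
}

# forward pass on a [H,W,1,N] batch; returns the predicted residual
dncnn_residual <- function(model, x, train = FALSE) {
  nn_forward(model$layers, x, train = train)
}

#' Denoise an image
#'
#' Runs the residual network in evaluation mode (batch normalization uses
#' running statistics) and subtracts the predicted residual from the
#' input. Any input size at least as large as the kernel is accepted; no
#' cropping or tiling is applied.
#'
#' @param model a [build_dncnn()] model
#' @param image an [image_plane()] or matrix
#' @return denoised [image_plane()] of identical size
#' @export
denoise <- function(model, image) {
  img <- as_image_plane(image)
  if (any(dim(img$pixels) < model$config$kernel))
    stop("image smaller than the convolution kernel")
  x <- array(norm01(img), c(dim(img$pixels), 1L, 1L))
  res <- dncnn_residual(model, x, train = FALSE)$out
  out <- matrix(x - res, nrow(img$pixels))
  image_plane(out * img$dynamic_range, img$dynamic_range)
}

# ---- checkpoints --------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single serialized weights file plus a JSON sidecar
#' (`<path>.json`) recording the architecture, the loss specification, the
#' seed and the training epoch.
#'
#' @param model a `dncnn` model
#' @param path file path for the weights
#' @param loss_spec,epoch optional metadata stored in the sidecar
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path, loss_spec = NULL, epoch = NA) {
  saveRDS(model, path)
  side <- list(config = unclass(model$config),
               seed = model$seed, epoch = epoch,
               loss = if (!is.null(loss_spec)) unclass(loss_spec))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dncnn")) stop("not a dncnn checkpoint: ", path)
  model
}
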