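# ------------------------------------------------------------------
# ImagePlane: the universal currency of the toolkit — a 2-D grayscale
# intensity matrix plus its declared dynamic range (the maximum
# representable value, 1.0 for images already normalized to [0, 1]).
# ------------------------------------------------------------------

#' Grayscale image with a declared dynamic range
#'
#' @param pixels numeric matrix of intensities (rows = image rows)
#' @param dynamic_range maximum representable intensity (> 0)
#' @return an `image_plane` object
#' @export
image_plane <- function(pixels, dynamic_range = 1) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("pixels must be a finite numeric matrix")
  if (dynamic_range <= 0) stop("dynamic_range must be positive")
  structure(list(pixels = pixels, dynamic_range = dynamic_range),
            class = "image_plane")
}

as_image_plane <- function(x, dynamic_range = 1) {
  if (inherits(x, "image_plane")) x else image_plane(x, dynamic_range)
}

# image on the [0,1] scale regardless of its declared range
norm01 <- function(img) {
  img <- as_image_plane(img)
  img$pixels / img$dynamic_range
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane %d x %d, dynamic range %g, values [%g, %g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) dim(x$pixels)
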