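# ------------------------------------------------------------------
# Sobel edge maps and gradient-traced edge widths.  These feed the
# no-reference sharpness metrics (PSI, JNB); per the JNB literature the
# tracing and contrast banding operate on a 0-255 working scale.
# ------------------------------------------------------------------

# reflect-pad by one pixel
pad_reflect1 <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

# 3x3 correlation with reflect border, kernel given as 3x3 matrix
filt3 <- function(m, k) {
  p <- pad_reflect1(m)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    kk <- k[di + 1, dj + 1]
    if (kk != 0)
      out <- out + kk * p[di + seq_len(h), dj + seq_len(w)]
  }
  out
}

sobel_gx <- function(m)
  filt3(m, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
sobel_gy <- function(m)
  filt3(m, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3))

#' Sobel edge map
#'
#' Applies horizontal and vertical 3x3 Sobel filters (reflect border) and
#' thresholds the gradient magnitude at a fraction of its maximum.
#'
#' @param image an [image_plane()] or matrix
#' @param threshold_frac edge threshold as a fraction of the maximum
#'   gradient magnitude, in (0, 1]
#' @return an `edge_map` list: `gx`, `gy`, `magnitude`, `edge_mask`,
#'   `threshold_used`
#' @export
edge_map <- function(image, threshold_frac = 0.1) {
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop("threshold_frac must be in (0, 1]")
  m <- as_image_plane(image)$pixels
  gx <- sobel_gx(m); gy <- sobel_gy(m)
  mag <- sqrt(gx^2 + gy^2)
  thr <- threshold_frac * max(mag)
  # guard against pure roundoff on (near-)constant images
  degenerate <- max(mag) <= 1e-9 * max(1, max(abs(m)))
  mask <- if (degenerate) matrix(FALSE, nrow(m), ncol(m)) else mag >= thr
  structure(list(gx = gx, gy = gy, magnitude = mag, edge_mask = mask,
                 threshold_used = thr),
            class = "edge_map")
}

#' Edge widths by gradient tracing
#'
#' For every detected edge pixel, traces along the dominant gradient axis
#' (rows for horizontal edges, columns for vertical ones) to the nearest
#' local intensity extremum on each side; the width is the pixel distance
#' between the two extrema and the contrast is their intensity difference.
#' Edge pixels with no room to trace are excluded.
#'
#' @param image an [image_plane()] or matrix; traced on the 0-255 scale
#' @param edges an [edge_map()] of the same image
#' @return data.frame with columns `row`, `col`, `width`, `contrast`
#'   (contrast on the 0-255 scale)
#' @export
edge_widths <- function(image, edges) {
  img255 <- norm01(image) * 255
  trace_edge_widths(img255, edges$edge_mask, edges$gx, edges$gy)
}
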