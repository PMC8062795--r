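# ------------------------------------------------------------------
# Block-based no-reference sharpness metrics: PSI and JNB.
# Both start from a Sobel edge map and gradient-traced edge widths.
# ------------------------------------------------------------------

#' PSI parameters
#'
#' @param block_size analysis tile side in pixels (>= 8)
#' @param gamma_percent percentile pool: the PSI is the mean of the highest
#'   `gamma_percent` percent of local sharpness values (default 22)
#' @param threshold_frac Sobel edge threshold fraction (see [edge_map()])
#' @return a `psi_params` list
#' @export
psi_params <- function(block_size = 32L, gamma_percent = 22,
                       threshold_frac = 0.1) {
  if (block_size < 8L) stop("block_size must be >= 8")
  if (gamma_percent <= 0 || gamma_percent > 100)
    stop("gamma_percent must be in (0, 100]")
  structure(list(block_size = as.integer(block_size),
                 gamma_percent = gamma_percent,
                 threshold_frac = threshold_frac),
            class = "psi_params")
}

#' JNB parameters
#'
#' @param block_size tile side in pixels (default 64)
#' @param edge_block_fraction a tile is an edge block when its edge-pixel
#'   count exceeds this fraction of its area (default 0.02)
#' @param beta probability-summation exponent (default 3.6)
#' @param w_low,w_high just-noticeable-blur widths for low- and
#'   high-contrast edges (defaults 5 and 3; must satisfy
#'   `3 <= w_high <= w_low <= 5`)
#' @param contrast_cut contrast (0-255 scale) separating the two width
#'   bands (default 51)
#' @param threshold_frac Sobel edge threshold fraction
#' @return a `jnb_params` list
#' @export
jnb_params <- function(block_size = 64L, edge_block_fraction = 0.02,
                       beta = 3.6, w_low = 5, w_high = 3,
                       contrast_cut = 51, threshold_frac = 0.1) {
  if (!(3 <= w_high && w_high <= w_low && w_low <= 5))
    stop("need 3 <= w_high <= w_low <= 5")
  if (edge_block_fraction <= 0 || edge_block_fraction >= 1)
    stop("edge_block_fraction must be in (0, 1)")
  structure(list(block_size = as.integer(block_size),
                 edge_block_fraction = edge_block_fraction, beta = beta,
                 w_low = w_low, w_high = w_high,
                 contrast_cut = contrast_cut,
                 threshold_frac = threshold_frac),
            class = "jnb_params")
}

# tile index (1-based) of each pixel position for a given block size
block_id <- function(i, j, bs, h, w) {
  bi <- (i - 1L) %/% bs
  bj <- (j - 1L) %/% bs
  bi + bj * ((h + bs - 1L) %/% bs) + 1L
}

#' Perceptual sharpness index
#'
#' Partitions the image into tiles; each tile containing at least one
#' measured edge width gets a local sharpness of 1 / (mean traced edge
#' width in the tile). The PSI is the mean of the highest `gamma_percent`
#' percent of those local values. Returns 0 (with a warning) when the
#' image has no measurable edges.
#'
#' @param image an [image_plane()] or matrix
#' @param params a [psi_params()]
#' @return unitless sharpness value (larger = sharper)
#' @export
psi <- function(image, params = psi_params()) {
  em <- edge_map(image, params$threshold_frac)
  ew <- edge_widths(image, em)
  if (nrow(ew) == 0) {
    warning("no measurable edges; PSI = 0")
    return(0)
  }
  d <- dim(as_image_plane(image)$pixels)
  ids <- block_id(ew$row, ew$col, params$block_size, d[1], d[2])
  local <- 1 / tapply(ew$width, ids, mean)
  k <- max(1L, ceiling(params$gamma_percent / 100 * length(local)))
  mean(sort(local, decreasing = TRUE)[seq_len(k)])
}

#' Just-noticeable-blur sharpness
#'
#' Tiles the image; a tile is an edge block when its Sobel edge-pixel count
#' exceeds `edge_block_fraction` of its area. Within each edge block the
#' perceived blur distortion pools the traced edge widths normalized by a
#' contrast-dependent just-noticeable width (`w_low` below `contrast_cut`,
#' `w_high` at or above it):
#' `D_Rb = (sum |w_i / w_jnb(i)|^beta)^(1/beta)`.
#' The image score divides the edge-block count by the pooled distortion:
#' `JNB = n_edge_blocks / (sum_b D_b^beta)^(1/beta)`; larger values mean
#' less perceived blur. Returns 0 with a warning when no edge blocks exist.
#'
#' @param image an [image_plane()] or matrix
#' @param params a [jnb_params()]
#' @return unitless sharpness value (larger = sharper)
#' @export
jnb <- function(image, params = jnb_params()) {
  em <- edge_map(image, params$threshold_frac)
  d <- dim(as_image_plane(image)$pixels)
  bs <- params$block_size
  nbl <- ((d[1] + bs - 1L) %/% bs) * ((d[2] + bs - 1L) %/% bs)
  # edge-pixel count per tile
  epx <- which(em$edge_mask, arr.ind = TRUE)
  if (nrow(epx) == 0) {
    warning("no edge blocks; JNB = 0")
    return(0)
  }
  ids <- block_id(epx[, 1], epx[, 2], bs, d[1], d[2])
  counts <- table(ids)
  # tile area (interior tiles bs^2; edge tiles smaller)
  tile_area <- function(id) {
    nbr <- (d[1] + bs - 1L) %/% bs
    bi <- (as.integer(id) - 1L) %% nbr
    bj <- (as.integer(id) - 1L) %/% nbr
    hr <- min(bs, d[1] - bi * bs); wc <- min(bs, d[2] - bj * bs)
    hr * wc
  }
  areas <- vapply(names(counts), tile_area, numeric(1))
  edge_blocks <- names(counts)[counts > params$edge_block_fraction * areas]
  if (length(edge_blocks) == 0) {
    warning("no edge blocks; JNB = 0")
    return(0)
  }
  ew <- edge_widths(image, em)
  if (nrow(ew) == 0) {
    warning("no measurable edges; JNB = 0")
    return(0)
  }
  ew$block <- block_id(ew$row, ew$col, bs, d[1], d[2])
  beta <- params$beta
  d_rb <- vapply(edge_blocks, function(b) {
    sel <- ew[ew$block == as.integer(b), ]
    if (nrow(sel) == 0) return(0)
    wj <- ifelse(sel$contrast < params$contrast_cut,
                 params$w_low, params$w_high)
    sum(abs(sel$width / wj)^beta)^(1 / beta)
  }, numeric(1))
  d_rb <- d_rb[d_rb > 0]
  if (length(d_rb) == 0) {
    warning("no measurable edges in edge blocks; JNB = 0")
    return(0)
  }
  length(d_rb) / sum(d_rb^beta)^(1 / beta)
}
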