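# ------------------------------------------------------------------
# Spectral and spatial sharpness (S3): a local sharpness map combining a
# magnitude-spectrum slope term (S1) with a local total-variation term
# (S2), pooled to a scalar by the maximum over the map.
# ------------------------------------------------------------------

#' S3 parameters
#'
#' @param s1_block spectral analysis block side (default 32, advanced on a
#'   50% overlapping grid, i.e. step `s1_block / 2`)
#' @param s2_block spatial (total-variation) tile side (default 8, step 4)
#' @param gamma_mix exponent mixing S1 and S2: `S3 = S1^g * S2^(1-g)`
#' @return an `s3_params` list
#' @export
s3_params <- function(s1_block = 32L, s2_block = 8L, gamma_mix = 0.5) {
  if (gamma_mix < 0 || gamma_mix > 1) stop("gamma_mix must be in [0, 1]")
  if (s1_block < 8L) stop("s1_block must be >= 8")
  structure(list(s1_block = as.integer(s1_block),
                 s2_block = as.integer(s2_block), gamma_mix = gamma_mix),
            class = "s3_params")
}

#' Magnitude-spectrum slope of a block
#'
#' Removes the block mean, Hann-windows the block, takes the 2-D DFT,
#' forms a radial profile of the
#' magnitude spectrum with a fixed number of samples per radial frequency
#' (rounded-radius ring means), and fits `log z(f) = log b - a * log f` by
#' least squares over `1 <= f <= Nyquist` (DC excluded). A constant block
#' has an empty spectrum and returns `Inf`, the maximally-blurred sentinel.
#'
#' @param block square numeric matrix (side >= 8) or [image_plane()]
#' @return the slope `alpha` (larger = steeper spectrum = blurrier)
#' @export
spectral_slope <- function(block) {
  m <- as_image_plane(block)$pixels
  n <- nrow(m)
  if (ncol(m) != n || n < 8) stop("block must be square with side >= 8")
  m <- m - mean(m)   # remove DC before windowing so it cannot leak into
  if (all(m == 0)) return(Inf)  # low-frequency bins and tilt the fit
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  wm <- m * outer(hann, hann)
  sp <- abs(stats::fft(wm))
  # frequency index of each DFT bin, 0..n/2 per axis
  fi <- c(0:(n %/% 2), rev(seq_len(n - n %/% 2 - 1)))
  rad <- round(sqrt(outer(fi^2, fi^2, "+")))
  nyq <- n %/% 2
  f <- seq_len(nyq)
  z <- vapply(f, function(r) mean(sp[rad == r]), numeric(1))
  if (all(z <= 0) || max(z) == 0) return(Inf)
  keep <- z > 0
  if (sum(keep) < 2) return(Inf)
  ft <- stats::lsfit(log(f[keep]), log(z[keep]))
  -unname(ft$coefficients[2])
}

#' Spectral sharpness term
#'
#' Maps a spectrum slope through the perceptual sigmoid
#' `S1 = 1 - 1 / (1 + exp(-3 * (alpha - 2)))`; slopes at or below 1 appear
#' sharp, larger slopes progressively blurred. The `Inf` sentinel of a
#' constant block maps to 0.
#'
#' @param alpha spectrum slope(s) from [spectral_slope()]
#' @return value(s) in (0, 1)
#' @export
s1_value <- function(alpha) {
  out <- 1 - 1 / (1 + exp(-3 * (alpha - 2)))
  out[is.infinite(alpha) & alpha > 0] <- 0
  out
}

#' Normalized total variation of a block
#'
#' Sum of absolute differences over all unordered 8-neighbor pixel pairs,
#' divided by 4 so that a maximal-contrast 2x2 checkerboard block scores
#' exactly 1.
#'
#' @param block numeric matrix (at least 2x2) on the `[0, 1]` scale
#' @return unitless value >= 0
#' @export
total_variation <- function(block) {
  m <- as_image_plane(block)$pixels
  h <- nrow(m); w <- ncol(m)
  if (h < 2 || w < 2) stop("block must be at least 2x2")
  s <- sum(abs(m[-1, ] - m[-h, ])) +                    # vertical pairs
    sum(abs(m[, -1] - m[, -w])) +                       # horizontal pairs
    sum(abs(m[-1, -1] - m[-h, -w])) +                   # diagonal
    sum(abs(m[-1, -w] - m[-h, -1]))                     # anti-diagonal
  s / 4
}

# max normalized TV over all 2x2 sub-blocks of a region, vectorized
max_tv2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 2 || w < 2) return(0)
  a <- m[-h, -w]; b <- m[-h, -1]; c_ <- m[-1, -w]; d <- m[-1, -1]
  tv <- (abs(a - b) + abs(a - c_) + abs(a - d) +
           abs(b - c_) + abs(b - d) + abs(c_ - d)) / 4
  max(tv)
}

#' Spatial sharpness map (S2)
#'
#' Per `s2_block` tile (advanced by `s2_block / 2`), the maximum normalized
#' total variation over all 2x2 sub-blocks of the tile. Values lie in
#' `[0, 1]` for images on the `[0, 1]` scale.
#'
#' @param image an [image_plane()] or matrix
#' @param params an [s3_params()]
#' @return list with `map` (matrix), `rows`, `cols` (tile top-left corners,
#'   1-based)
#' @export
s2_map <- function(image, params = s3_params()) {
  m <- norm01(image)
  bs <- params$s2_block; step <- max(1L, bs %/% 2L)
  rs <- grid_starts(nrow(m), bs, step)
  cs <- grid_starts(ncol(m), bs, step)
  map <- matrix(0, length(rs), length(cs))
  for (a in seq_along(rs)) for (b in seq_along(cs))
    map[a, b] <- max_tv2(m[rs[a]:(rs[a] + bs - 1), cs[b]:(cs[b] + bs - 1)])
  list(map = map, rows = rs, cols = cs)
}

# top-left corners covering [1, n] with block bs and step, last block
# clamped inside
grid_starts <- function(n, bs, step) {
  if (n < bs) stop("image smaller than block")
  s <- seq(1L, n - bs + 1L, by = step)
  if (s[length(s)] != n - bs + 1L) s <- c(s, n - bs + 1L)
  s
}

#' Spectral and spatial sharpness (S3)
#'
#' Computes the S1 map from per-block spectrum slopes on a 50%-overlapping
#' `s1_block` grid, the S2 map from local total variation, combines them as
#' `S3 = S1^gamma_mix * S2^(1 - gamma_mix)` on the S1 grid (S2 pooled by
#' max over each S1 block), and pools the map by its maximum. Also reports
#' the spectrum slope of the arg-max block.
#'
#' @param image an [image_plane()] or matrix, larger than `s1_block`
#' @param params an [s3_params()]
#' @return list: `scalar`, `map` (S3 map on the S1 grid), `alpha_global`
#'   (slope of the sharpest block), `s1_map`, `s2_map`
#' @export
s3 <- function(image, params = s3_params()) {
  m <- norm01(image)
  bs <- params$s1_block; step <- max(1L, bs %/% 2L)
  rs <- grid_starts(nrow(m), bs, step)
  cs <- grid_starts(ncol(m), bs, step)
  alpha <- matrix(Inf, length(rs), length(cs))
  s2m <- matrix(0, length(rs), length(cs))
  for (a in seq_along(rs)) for (b in seq_along(cs)) {
    blk <- m[rs[a]:(rs[a] + bs - 1), cs[b]:(cs[b] + bs - 1)]
    alpha[a, b] <- spectral_slope(blk)
    s2m[a, b] <- max_tv2(blk)
  }
  s1m <- s1_value(alpha)
  g <- params$gamma_mix
  map <- s1m^g * s2m^(1 - g)
  best <- which.max(map)
  list(scalar = map[best], map = map, alpha_global = alpha[best],
       s1_map = s1m, s2_map = s2m)
}
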