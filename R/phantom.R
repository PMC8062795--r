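# ------------------------------------------------------------------
# Layered retinal B-scan phantoms with multiplicative speckle.
#
# The simulator stands in for clinical OCT pairs: one speckled frame plays
# the role of the acquired noisy B-scan, and the pixelwise mean of several
# independently speckled frames of the same phantom plays the role of the
# registered-and-averaged reference.  Registration is assumed perfect.
# ------------------------------------------------------------------

#' Phantom configuration
#'
#' Describes a layered retina-like cross-section: horizontal bands of
#' constant mean reflectivity separated by smooth boundaries, optionally
#' perturbed by sinusoidal waviness, a centered foveal depression, and
#' vertical vessel shadows.
#'
#' @param height,width image size in pixels
#' @param n_layers number of bands (>= 2); one intensity per band
#' @param layer_intensities mean reflectivities in `[0, 1]`, one per band.
#'   The default emulates a macular B-scan: dark vitreous on top, alternating
#'   bright/dim retinal layers, a bright RPE-like band, dark choroid below.
#' @param boundary_waviness amplitude (pixels) of a smooth sinusoidal
#'   perturbation applied independently to each boundary; the default
#'   scales with image height (2 px at the default 256-px height)
#' @param foveal_dip amplitude (pixels) of a centered Gaussian depression
#'   applied to all boundaries (0 disables); the default scales with image
#'   height (10 px at 256)
#' @param vessel_shadows number of vertical dark shadow columns (0 disables)
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   phantom
#' @return a `phantom_config` list
#' @export
phantom_config <- function(height = 256L, width = 256L, n_layers = 6L,
                           layer_intensities = c(0.04, 0.55, 0.30,
                                                 0.60, 0.75, 0.08),
                           boundary_waviness = height / 128,
                           foveal_dip = height / 25.6,
                           vessel_shadows = 2L, seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_layers = as.integer(n_layers),
              layer_intensities = as.numeric(layer_intensities),
              boundary_waviness = boundary_waviness,
              foveal_dip = foveal_dip,
              vessel_shadows = as.integer(vessel_shadows),
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_layers < 2L)
    stop("phantom needs at least 2 bands (n_layers >= 2)")
  if (length(cfg$layer_intensities) != cfg$n_layers)
    stop("layer_intensities must have one value per band")
  if (any(cfg$layer_intensities < 0 | cfg$layer_intensities > 1))
    stop("layer_intensities must lie in [0, 1]")
  if (cfg$height < 8L || cfg$width < 8L) stop("phantom too small")
  if (cfg$boundary_waviness < 0 || cfg$foveal_dip < 0)
    stop("waviness and foveal_dip must be non-negative")
  invisible(cfg)
}

#' Speckle configuration
#'
#' Fully developed multiplicative speckle with a gamma number-of-looks
#' model: each pixel is multiplied by an i.i.d. Gamma(shape = looks,
#' scale = 1/looks) factor, which has unit mean and variance 1/looks.
#'
#' @param looks positive number of looks L; smaller L means heavier speckle
#' @param n_frames number of independent frames averaged into the reference
#' @param seed integer master seed; each frame uses a stream derived from it
#' @return a `speckle_config` list
#' @export
speckle_config <- function(looks = 4, n_frames = 8L, seed = 1L) {
  if (looks <= 0) stop("looks must be > 0")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  structure(list(looks = looks, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "speckle_config")
}

# smooth per-boundary row curves; returns width x (n_layers - 1) matrix
phantom_boundaries <- function(cfg) {
  nb <- cfg$n_layers - 1L
  h <- cfg$height; w <- cfg$width
  top <- 0.15 * h; bot <- 0.85 * h
  base <- seq(top, bot, length.out = nb)
  xs <- seq_len(w)
  dip <- cfg$foveal_dip * exp(-((xs - (w + 1) / 2)^2) / (2 * (w / 8)^2))
  B <- matrix(0, nrow = w, ncol = nb)
  for (b in seq_len(nb)) {
    phase <- runif(1, 0, 2 * pi)
    freq <- runif(1, 1, 2.5)
    wav <- cfg$boundary_waviness * sin(2 * pi * freq * xs / w + phase)
    B[, b] <- base[b] + wav + dip
  }
  if (any(B < 0.5) || any(B > h - 1.5))
    stop("boundaries leave the image after waviness/foveal dip")
  if (nb > 1 && any(B[, -1, drop = FALSE] - B[, -nb, drop = FALSE] <= 0))
    stop("boundaries would cross after waviness/foveal dip")
  colnames(B) <- paste0("boundary_", seq_len(nb))
  B
}

#' Generate a noiseless layered phantom
#'
#' Renders the piecewise-constant band image with linear sub-pixel coverage
#' over one row at each boundary (finite-width transitions are required by
#' the edge-width based sharpness metrics), and returns the exact boundary
#' rows used.
#'
#' @param cfg a [phantom_config()]
#' @return list with `image` (an [image_plane()]) and `boundaries` (a
#'   `boundary_set`: named list of per-column row vectors, 0-based)
#' @export
generate_phantom <- function(cfg) {
  validate_phantom_config(cfg)
  set.seed(cfg$seed)
  B <- phantom_boundaries(cfg)
  h <- cfg$height; w <- cfg$width
  nb <- ncol(B)
  img <- matrix(0, h, w)
  ints <- cfg$layer_intensities
  rows <- seq_len(h) - 1  # pixel r covers [r, r + 1)
  for (j in seq_len(w)) {
    cuts <- c(-Inf, B[j, ], Inf)
    col <- numeric(h)
    for (band in seq_len(nb + 1L)) {
      lo <- cuts[band]; hi <- cuts[band + 1L]
      cov <- pmin(rows + 1, hi) - pmax(rows, lo)
      cov <- pmin(pmax(cov, 0), 1)
      col <- col + cov * ints[band]
    }
    img[, j] <- col
  }
  if (cfg$vessel_shadows > 0L) {
    centers <- runif(cfg$vessel_shadows, 0.1 * w, 0.9 * w)
    atten <- rep(1, w)
    for (cx in centers)
      atten <- atten * (1 - 0.6 * exp(-((seq_len(w) - cx)^2) / (2 * 3^2)))
    below <- outer(rows, B[, 1], ">=")  # h x w: below the first boundary
    img <- img * (1 - below) + img * below * rep(atten, each = h)
  }
  bset <- lapply(seq_len(nb), function(b) B[, b])
  names(bset) <- colnames(B)
  class(bset) <- "boundary_set"
  list(image = image_plane(img, dynamic_range = 1),
       boundaries = bset)
}

# frame streams are derived from the master seed by a fixed offset so any
# frame is reproducible on its own
frame_seed <- function(seed, frame_index) {
  (as.integer(seed) + 10007L * as.integer(frame_index)) %% .Machine$integer.max
}

#' Apply multiplicative gamma speckle
#'
#' Multiplies the image by i.i.d. unit-mean Gamma(shape = L, scale = 1/L)
#' factors. Different `frame_index` values with the same seed give
#' independent, individually reproducible draws. Values are not clipped.
#'
#' @param image an [image_plane()] or matrix with non-negative values
#' @param cfg a [speckle_config()]
#' @param frame_index which independent frame to draw (0, 1, 2, ...)
#' @return speckled [image_plane()]
#' @export
apply_speckle <- function(image, cfg, frame_index = 0L) {
  img <- as_image_plane(image)
  if (cfg$looks <= 0) stop("looks must be > 0")
  if (any(img$pixels < 0)) stop("speckle needs non-negative intensities")
  set.seed(frame_seed(cfg$seed, frame_index))
  m <- matrix(stats::rgamma(length(img$pixels), shape = cfg$looks,
                            rate = cfg$looks),
              nrow = nrow(img$pixels))
  image_plane(img$pixels * m, img$dynamic_range)
}

#' Synthesize a noisy/averaged B-scan pair
#'
#' The noisy image is one speckled frame; the reference is the pixelwise
#' mean of `n_frames` further independent frames of the same phantom,
#' emulating a registered-and-averaged acquisition. The noiseless phantom
#' and its boundaries are attached for synthetic-data diagnostics.
#'
#' @param phantom_cfg a [phantom_config()]
#' @param speckle_cfg a [speckle_config()]
#' @return an `image_pair` list: `noisy`, `reference`, `clean`, `boundaries`
#' @export
synthesize_pair <- function(phantom_cfg, speckle_cfg) {
  ph <- generate_phantom(phantom_cfg)
  noisy <- apply_speckle(ph$image, speckle_cfg, frame_index = 0L)
  acc <- matrix(0, phantom_cfg$height, phantom_cfg$width)
  for (f in seq_len(speckle_cfg$n_frames))
    acc <- acc + apply_speckle(ph$image, speckle_cfg, frame_index = f)$pixels
  ref <- image_plane(acc / speckle_cfg$n_frames, noisy$dynamic_range)
  structure(list(noisy = noisy, reference = ref,
                 clean = ph$image, boundaries = ph$boundaries),
            class = "image_pair")
}
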