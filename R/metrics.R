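# ------------------------------------------------------------------
# Reference-based quality metrics: PSNR and the per-boundary
# edge-preserving index (EPI).
# ------------------------------------------------------------------

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB, with the peak taken as the declared
#' dynamic range of the reference (bit-depth convention), so the value does
#' not depend on the content of the test image. Identical images return
#' `Inf`.
#'
#' @param test,reference [image_plane()] objects (or matrices, assumed to
#'   share dynamic range 1) of identical size
#' @return PSNR in dB
#' @export
psnr <- function(test, reference) {
  t_ <- as_image_plane(test); r_ <- as_image_plane(reference)
  if (!identical(dim(t_$pixels), dim(r_$pixels)))
    stop("test and reference must have identical dimensions")
  if (t_$dynamic_range != r_$dynamic_range)
    stop("test and reference must share a dynamic range")
  mse <- mean((t_$pixels - r_$pixels)^2)
  if (mse == 0) return(Inf)
  10 * log10(r_$dynamic_range^2 / mse)
}

#' Edge-preserving index at layer boundaries
#'
#' For each annotated boundary, accumulates the absolute vertical
#' (row-direction) intensity difference across the boundary:
#' `EPI = sum_j |Id(i+1, j) - Id(i, j)|` with `i` the boundary row rounded
#' to the nearest pixel and `Id` the image normalized to `[0, 1]`. Only
#' row-direction differences are used because retinal boundaries are
#' horizontal structures. Columns whose boundary sits on the last row are
#' skipped (and counted in the `skipped` attribute).
#'
#' @param image an [image_plane()] or matrix
#' @param boundaries a `boundary_set`: named list of per-column 0-based
#'   boundary rows (as produced by [generate_phantom()] or
#'   [read_boundaries()])
#' @return named numeric vector of EPI values, one per boundary
#' @export
epi <- function(image, boundaries) {
  id <- norm01(image)
  h <- nrow(id); w <- ncol(id)
  out <- numeric(length(boundaries))
  names(out) <- names(boundaries)
  skipped <- 0L
  for (b in seq_along(boundaries)) {
    rows <- boundaries[[b]]
    if (length(rows) != w)
      stop("boundary '", names(boundaries)[b],
           "' must have one row per image column")
    i <- round(rows) + 1  # to 1-based
    if (any(i < 1 | i > h)) stop("boundary rows outside the image")
    ok <- i + 1 <= h
    skipped <- skipped + sum(!ok)
    j <- which(ok)
    out[b] <- sum(abs(id[cbind(i[j] + 1, j)] - id[cbind(i[j], j)]))
  }
  attr(out, "skipped") <- skipped
  out
}
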