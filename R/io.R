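# ------------------------------------------------------------------
# Image, annotation and manifest I/O.  Images are 8/16-bit grayscale PNG
# or TIFF; intensities are scaled to [0, 1] on load with the bit-depth
# recorded as the dynamic range.  Boundary annotations travel as CSV with
# columns boundary,column,row (0-based).
# ------------------------------------------------------------------

#' Load a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF. RGB images are collapsed to
#' luminance with a warning. Intensities are returned on `[0, 1]`; the
#' bit depth is recorded in the `bit_depth` attribute.
#'
#' @param path image file path
#' @return an [image_plane()] with dynamic range 1
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              png = try(png::readPNG(path, info = TRUE), silent = TRUE),
              tif = , tiff = try(tiff::readTIFF(path), silent = TRUE),
              stop("unsupported image format: ", path))
  if (inherits(m, "try-error")) stop("cannot read image: ", path)
  bits <- if (ext == "png" && !is.null(attr(m, "info")))
    attr(m, "info")$bit.depth else 16L
  if (length(dim(m)) == 3) {
    warning("RGB image collapsed to luminance: ", path)
    m <- 0.2126 * m[, , 1] + 0.7152 * m[, , 2] + 0.0722 * m[, , 3]
  }
  img <- image_plane(m, dynamic_range = 1)
  attr(img, "bit_depth") <- bits
  img
}

#' Save a grayscale image
#'
#' Writes 16-bit TIFF (default, avoids quantizing denoiser outputs) or
#' 8-bit PNG, chosen by extension. Values are clipped to the dynamic
#' range at export.
#'
#' @param image an [image_plane()] or matrix
#' @param path output path ending in `.tif`/`.tiff` or `.png`
#' @return `path`, invisibly
#' @export
save_image <- function(image, path) {
  v <- pmin(pmax(norm01(image), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(v, path),
         tif = , tiff = tiff::writeTIFF(v, path, bits.per.sample = 16L),
         stop("unsupported image format: ", path))
  invisible(path)
}

#' Read / write boundary annotations
#'
#' CSV format: header `boundary,column,row` with 0-based column indices
#' and real-valued 0-based rows; one row entry per image column per
#' boundary.
#'
#' @param path CSV path
#' @return a `boundary_set`: named list of per-column row vectors
#' @export
read_boundaries <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("boundary", "column", "row")
  if (!all(need %in% names(df)))
    stop("boundary CSV needs columns boundary,column,row: ", path)
  out <- lapply(split(df, df$boundary), function(d)
    d$row[order(d$column)])
  class(out) <- "boundary_set"
  out
}

#' @rdname read_boundaries
#' @param boundaries a `boundary_set`
#' @export
write_boundaries <- function(boundaries, path) {
  df <- do.call(rbind, lapply(names(boundaries), function(nm)
    data.frame(boundary = nm,
               column = seq_along(boundaries[[nm]]) - 1L,
               row = boundaries[[nm]])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' CSV with columns `noisy,reference,boundaries,split`; all referenced
#' paths (resolved relative to the manifest) must exist, and splits must
#' be train/val/test.
#'
#' @param path manifest CSV path
#' @return data.frame with absolute paths
#' @export
read_manifest <- function(path) {
  mf <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("noisy", "reference", "split") %in% names(mf)))
    stop("manifest needs columns noisy,reference,split: ", path)
  if (!all(mf$split %in% c("train", "val", "test")))
    stop("manifest split values must be train/val/test")
  base <- dirname(path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  for (cl in intersect(c("noisy", "reference", "boundaries"), names(mf))) {
    filled <- !is.na(mf[[cl]]) & nzchar(mf[[cl]])
    mf[[cl]][filled] <- fix(mf[[cl]][filled])
    missing <- filled & !file.exists(mf[[cl]])
    if (any(missing))
      stop("manifest references missing file(s): ",
           paste(mf[[cl]][missing], collapse = ", "))
  }
  mf
}
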