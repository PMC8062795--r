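# ------------------------------------------------------------------
# Sharpness reports: per-image assembly of PSNR / PSI / JNB / S3 /
# per-boundary EPI, and batch (manifest) evaluation.
# ------------------------------------------------------------------

#' Evaluate all sharpness metrics on one image
#'
#' Computes the no-reference metrics (PSI, JNB, S3 and the global spectrum
#' slope) always, PSNR when a reference is given, and per-boundary EPI
#' when boundary annotations are given.
#'
#' @param image an [image_plane()] or matrix (e.g. a denoised B-scan)
#' @param reference optional reference image for PSNR
#' @param boundaries optional `boundary_set` for EPI
#' @param psi,jnbp,s3p metric parameter objects
#' @return a `sharpness_report` list: `psnr` (or `NA`), `psi`, `jnb`,
#'   `s3`, `alpha_global`, `epi` (named vector or `NULL`)
#' @export
evaluate_sharpness <- function(image, reference = NULL, boundaries = NULL,
                               psi = psi_params(), jnbp = jnb_params(),
                               s3p = s3_params()) {
  s3r <- s3(image, s3p)
  rep_ <- list(
    psnr = if (!is.null(reference)) psnr(image, reference) else NA_real_,
    psi = psi(image, psi),
    jnb = jnb(image, jnbp),
    s3 = s3r$scalar,
    alpha_global = s3r$alpha_global,
    epi = if (!is.null(boundaries)) epi(image, boundaries))
  class(rep_) <- "sharpness_report"
  rep_
}

# flatten a report to a one-row data.frame (epi_<name> columns)
report_row <- function(rep_) {
  row <- data.frame(psnr = rep_$psnr, psi = rep_$psi, jnb = rep_$jnb,
                    s3 = rep_$s3, alpha = rep_$alpha_global)
  if (!is.null(rep_$epi)) {
    ev <- as.numeric(rep_$epi)
    names(ev) <- paste0("epi_", names(rep_$epi))
    row <- cbind(row, as.data.frame(as.list(ev)))
  }
  row
}

#' @export
print.sharpness_report <- function(x, ...) {
  cat("<sharpness_report>\n")
  cat(sprintf("  psnr: %s dB\n",
              if (is.na(x$psnr)) "absent" else format(x$psnr, digits = 5)))
  cat(sprintf("  psi:  %.4f   jnb: %.4f   s3: %.4f   alpha: %.3f\n",
              x$psi, x$jnb, x$s3, x$alpha_global))
  if (!is.null(x$epi)) {
    cat("  epi: ", paste(sprintf("%s=%.3f", names(x$epi), x$epi),
                         collapse = "  "), "\n")
  }
  invisible(x)
}

#' Batch evaluation from a manifest
#'
#' Reads a manifest CSV with columns `noisy,reference,boundaries`
#' (reference and boundaries may be empty), evaluates each image —
#' optionally denoising first with a checkpoint — and writes a report CSV
#' with columns `image,psnr,psi,jnb,s3,alpha,epi_<boundary>...` plus a
#' mean row. Images without boundary files simply lack EPI columns.
#'
#' @param manifest path to the manifest CSV or a data.frame
#' @param out optional path for the report CSV
#' @param model optional `dncnn` model or checkpoint path; when given the
#'   noisy image is denoised before evaluation
#' @param psi,jnbp,s3p metric parameter objects
#' @return the report data.frame, invisibly when `out` is given
#' @export
evaluate_manifest <- function(manifest, out = NULL, model = NULL,
                              psi = psi_params(), jnbp = jnb_params(),
                              s3p = s3_params()) {
  mf <- if (is.character(manifest)) {
    read.csv(manifest, stringsAsFactors = FALSE)
  } else manifest
  if (!"noisy" %in% names(mf)) stop("manifest needs a 'noisy' column")
  base <- if (is.character(manifest)) dirname(manifest) else "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  if (is.character(model)) model <- load_checkpoint(model)
  rows <- lapply(seq_len(nrow(mf)), function(i) {
    img <- load_image(resolve(mf$noisy[i]))
    if (!is.null(model)) img <- denoise(model, img)
    ref <- NULL; bnd <- NULL
    if (!is.null(mf$reference) && !is.na(mf$reference[i]) &&
        nzchar(mf$reference[i]))
      ref <- load_image(resolve(mf$reference[i]))
    if (!is.null(mf$boundaries) && !is.na(mf$boundaries[i]) &&
        nzchar(mf$boundaries[i]))
      bnd <- read_boundaries(resolve(mf$boundaries[i]))
    r <- evaluate_sharpness(img, ref, bnd, psi, jnbp, s3p)
    cbind(data.frame(image = basename(mf$noisy[i])), report_row(r))
  })
  # align columns (images with and without boundaries)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(cols, names(r))) r[[cl]] <- NA_real_
    r[cols]
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab[, -1, drop = FALSE],
                function(v) mean(v, na.rm = TRUE), numeric(1))
  tab <- rbind(tab, cbind(data.frame(image = "mean"),
                          as.data.frame(as.list(num))))
  rownames(tab) <- NULL
  if (!is.null(out)) {
    write.csv(tab, out, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
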