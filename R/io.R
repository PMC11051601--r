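# Frame and localization I/O. Frames travel as 32-bit float TIFF stacks
# (multi-page, one page per frame); localizations and tracks as CSV.

#' Write frames as a multi-page 32-bit float TIFF
#'
#' TIFF sample values are confined to \[0, 1\], so intensities are stored
#' multiplied by `scale`; [read_frames_tiff()] divides it back out. The
#' default accommodates normalized holographic intensities up to 4 (the
#' background sits at 1).
#'
#' @param frames List of numeric matrices (identical geometry).
#' @param path Output `.tif` path.
#' @param scale Stored value = intensity * scale. Default 0.25.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path, scale = 0.25) {
  stopifnot(is.list(frames), length(frames) > 0)
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f * scale, 0), 1)),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a list of matrices
#'
#' @param path `.tif` path.
#' @param scale Inverse of the scale used when writing. Default 0.25.
#' @return Named list of numeric matrices (names `"0", "1", ...`).
#' @export
read_frames_tiff <- function(path, scale = 0.25) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p / scale
  })
  names(pages) <- as.character(seq_along(pages) - 1L)
  pages
}

#' Write / read localizations as CSV
#'
#' Columns `frame`, `x_um`, `y_um`, `z_um`, `response`, `source` (missing
#' optional columns are omitted/filled).
#'
#' @param localizations Tibble of localizations.
#' @param path CSV path.
#' @export
write_localizations <- function(localizations, path) {
  loc <- tibble::as_tibble(localizations)
  cols <- intersect(c("frame", "x_um", "y_um", "z_um", "response", "source"),
                    names(loc))
  readr::write_csv(dplyr::select(loc, dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
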