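# Background estimation and per-frame normalization. A per-pixel median over
# the frames of a video captures everything static (illumination profile,
# dust, diffraction from optics) while excluding the moving cells; dividing
# each frame by the median image centres the background at 1 and leaves only
# the cells' interference fringes.

#' Per-pixel median background of a video
#'
#' Each output pixel is the median, over frames, of that pixel's intensity.
#' Moving objects occupy any one pixel only transiently, so they drop out of
#' the median while static structure is retained.
#'
#' @param frames List of numeric matrices (identical geometry), or a 3D array
#'   with frames along the third dimension. At least 3 frames.
#' @param first_n Optionally use only the first `first_n` frames (a live
#'   pipeline can build its background from the first few frames of a video).
#' @return A matrix of class `median_background` with attribute
#'   `n_source_frames`.
#' @export
compute_median_background <- function(frames, first_n = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  stopifnot(is.list(frames))
  if (!is.null(first_n)) frames <- frames[seq_len(min(first_n, length(frames)))]
  if (length(frames) < 3) {
    rlang::abort("need at least 3 frames to form a median background")
  }
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    rlang::abort("all frames must share the same geometry")
  }
  stacked <- vapply(frames, as.numeric, numeric(prod(d)))  # pixels x frames
  med <- matrix(matrixStats::rowMedians(stacked), d[1], d[2])
  structure(med, class = c("median_background", "matrix", "array"),
            n_source_frames = length(frames))
}

#' Normalize a frame by the median background
#'
#' Elementwise ratio `frame / background`. Background pixels below a floor
#' (a small fraction of the background's median level, guarding dead pixels)
#' are clamped to the floor before division; the number of clamped pixels is
#' reported in attribute `n_floored`.
#'
#' @param frame Numeric matrix.
#' @param background A [compute_median_background()] result (or any matrix of
#'   matching geometry).
#' @param floor_frac Floor as a fraction of `median(background)`.
#'   Default 1e-6.
#' @return Normalized matrix (background level 1) with attribute `n_floored`.
#' @export
normalize_frame <- function(frame, background, floor_frac = 1e-6) {
  stopifnot(is.matrix(frame))
  bg <- unclass(background)
  if (!identical(dim(frame), dim(bg))) {
    rlang::abort("frame and background geometry differ")
  }
  floor_val <- floor_frac * stats::median(bg)
  if (!is.finite(floor_val) || floor_val <= 0) floor_val <- floor_frac
  low <- bg < floor_val
  bg[low] <- floor_val
  out <- frame / bg
  attr(out, "n_floored") <- sum(low)
  out
}
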