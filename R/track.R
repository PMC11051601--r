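# Link per-frame 3D localizations into tracks. Frame-to-frame
# correspondence is the optimal bipartite assignment minimizing total 3D
# Euclidean distance (Hungarian algorithm), subject to a per-link distance
# gate; unmatched tracks persist across short gaps; short tracks are
# discarded, which rejects spurious transient detections.

BIG_COST <- 1e9

#' Link localizations into 3D tracks
#'
#' @param localizations Tibble with `frame`, `x_um`, `y_um`, `z_um` (other
#'   columns are carried through).
#' @param max_disp Maximum 3D displacement per link, um. Default 30
#'   (about the largest per-frame displacement of a fast swimmer at 30 Hz).
#' @param max_gap Frames a track may go unmatched before termination.
#'   Default 2.
#' @param min_length Minimum number of localizations for a track to be
#'   kept. Default 5.
#' @return The surviving localizations with a `track` column, ordered by
#'   track then frame. Tracks are numbered consecutively from 1 in order of
#'   first appearance.
#' @export
link_tracks <- function(localizations, max_disp = 30, max_gap = 2L,
                        min_length = 5L) {
  loc <- tibble::as_tibble(localizations)
  stopifnot(all(c("frame", "x_um", "y_um", "z_um") %in% names(loc)),
            max_disp > 0, max_gap >= 0, min_length >= 1)
  if (nrow(loc) == 0) return(dplyr::mutate(loc, track = integer(0)))
  loc <- dplyr::arrange(loc, .data$frame)
  frames <- sort(unique(loc$frame))
  track_of_row <- integer(nrow(loc))
  # active track state
  act_id <- integer(0); act_pos <- matrix(0, 0, 3); act_last <- integer(0)
  next_id <- 1L
  row_idx <- split(seq_len(nrow(loc)), loc$frame)
  for (f in frames) {
    rows <- row_idx[[as.character(f)]]
    P <- cbind(loc$x_um[rows], loc$y_um[rows], loc$z_um[rows])
    live <- which(f - act_last <= max_gap + 1L)
    assigned_det <- rep(NA_integer_, length(rows))
    if (length(live) > 0 && length(rows) > 0) {
      D <- sqrt(outer(act_pos[live, 1], P[, 1], `-`)^2 +
                outer(act_pos[live, 2], P[, 2], `-`)^2 +
                outer(act_pos[live, 3], P[, 3], `-`)^2)
      C <- ifelse(D <= max_disp, D, BIG_COST)
      nr <- nrow(C); ncl <- ncol(C)
      if (nr <= ncl) {
        sol <- as.integer(clue::solve_LSAP(C))
        for (i in seq_len(nr)) {
          j <- sol[i]
          if (C[i, j] < BIG_COST / 2) assigned_det[j] <- live[i]
        }
      } else {
        sol <- as.integer(clue::solve_LSAP(t(C)))
        for (j in seq_len(ncl)) {
          i <- sol[j]
          if (C[i, j] < BIG_COST / 2) assigned_det[j] <- live[i]
        }
      }
    }
    for (j in seq_along(rows)) {
      k <- assigned_det[j]
      if (is.na(k)) {
        act_id <- c(act_id, next_id)
        act_pos <- rbind(act_pos, P[j, ])
        act_last <- c(act_last, f)
        track_of_row[rows[j]] <- next_id
        next_id <- next_id + 1L
      } else {
        act_pos[k, ] <- P[j, ]
        act_last[k] <- f
        track_of_row[rows[j]] <- act_id[k]
      }
    }
  }
  loc$track <- track_of_row
  keep <- loc |>
    dplyr::count(.data$track) |>
    dplyr::filter(.data$n >= min_length) |>
    dplyr::pull(.data$track)
  out <- dplyr::filter(loc, .data$track %in% keep)
  out$track <- match(out$track, unique(out$track))
  dplyr::arrange(out, .data$track, .data$frame)
}

#' RMSE between two tracks over their common frames
#'
#' Root mean squared 3D point-to-point distance over frames present in both
#' tracks; at least 3 common frames are required.
#'
#' @param predicted,reference Tibbles with `frame`, `x_um`, `y_um`, `z_um`
#'   (single tracks).
#' @return RMSE in um.
#' @export
track_rmse <- function(predicted, reference) {
  j <- dplyr::inner_join(tibble::as_tibble(predicted),
                         tibble::as_tibble(reference),
                         by = "frame", suffix = c("", ".ref"))
  if (nrow(j) < 3) {
    rlang::abort("tracks share fewer than 3 frames; RMSE undefined")
  }
  sqrt(mean((j$x_um - j$x_um.ref)^2 + (j$y_um - j$y_um.ref)^2 +
              (j$z_um - j$z_um.ref)^2))
}

#' Pair predicted tracks with reference tracks
#'
#' Each predicted track is paired with the reference track it shares the
#' most frames with (ties broken by smaller RMSE); pairs with fewer than 3
#' common frames are dropped.
#'
#' @param predicted Tibble with `track`, `frame`, `x_um`, `y_um`, `z_um`.
#' @param reference Tibble with the same columns (e.g. ground truth with
#'   `cell` renamed to `track`).
#' @return Tibble with `track`, `track_ref`, `n_common`, `rmse_um`.
#' @export
match_tracks <- function(predicted, reference) {
  pred <- tibble::as_tibble(predicted)
  ref <- tibble::as_tibble(reference)
  stopifnot("track" %in% names(pred), "track" %in% names(ref))
  rows <- purrr::map(unique(pred$track), function(tid) {
    p <- dplyr::filter(pred, .data$track == tid)
    ov <- ref |>
      dplyr::semi_join(p, by = "frame") |>
      dplyr::count(.data$track, name = "n_common") |>
      dplyr::filter(.data$n_common >= 3)
    if (nrow(ov) == 0) return(NULL)
    ov$rmse_um <- vapply(ov$track, function(rt) {
      track_rmse(p, dplyr::filter(ref, .data$track == rt))
    }, numeric(1))
    best <- ov[order(-ov$n_common, ov$rmse_um), ][1, ]
    tibble::tibble(track = tid, track_ref = best$track,
                   n_common = best$n_common, rmse_um = best$rmse_um)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(track = integer(), track_ref = integer(),
                          n_common = integer(), rmse_um = double())
  }
  out
}

#' Write / read tracks as CSV
#'
#' Columns `track`, `frame`, `x_um`, `y_um`, `z_um` and, when present,
#' `source`.
#'
#' @param tracks Tibble from [link_tracks()].
#' @param path CSV file path.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("track", "frame", "x_um", "y_um", "z_um", "source"),
                    names(tracks))
  readr::write_csv(dplyr::select(tibble::as_tibble(tracks),
                                 dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
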