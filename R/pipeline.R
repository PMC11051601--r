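# End-to-end orchestration: a single config drives simulate -> preprocess ->
# calibrate -> annotate -> detect -> depth-correct -> track -> evaluate,
# writing every artifact into a run directory. Stages are deterministic
# under the config seed; each run logs the config hash so artifacts are
# traceable to the exact configuration that produced them.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    optics = list(wavelength = 0.642, medium_index = 1.33,
                  pixel_pitch = 360 / 512, frame_width = 512L,
                  frame_height = 512L, frame_rate = 30,
                  chamber_depth = 280),
    simulation = list(n_cells = 40L, n_frames = 100L, speed = 20,
                      tumble_rate = 1, diffusion = 0.4, amplitude = 0.15,
                      noise_sd = 0.002, artifact = TRUE,
                      n_validation_frames = 60L),
    reconstruction = list(dz = 2, z_max = NULL, threshold = 8,
                          min_voxels = 4L, smooth = TRUE, apodize_px = 16L),
    calibration = list(z_lo = 50, z_hi = 200, offset = NULL, min_box = 12,
                       z_grid = seq(20, 260, by = 10)),
    detection = list(z_templates = template_depths(),
                     score_threshold = 0.3, nms_iou = 0.45,
                     support_px = 32, merge_px = 8,
                     box_side = "pattern"),
    correction = list(order = 4L, max_lateral_um = 6),
    tracking = list(max_disp = 30, max_gap = 2L, min_length = 5L),
    evaluation = list(score_threshold = 0)
  )
}

merge_block <- function(defaults, user, path) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config key(s) under %s: %s", path,
                         paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, user)
}

#' Build a validated pipeline configuration
#'
#' Starts from package defaults and overlays the supplied blocks; unknown
#' keys anywhere are rejected. See `pipeline_defaults()` in the source for
#' the full set of tunables.
#'
#' @param ... Named blocks (`seed`, `optics`, `simulation`,
#'   `reconstruction`, `calibration`, `detection`, `correction`,
#'   `tracking`, `evaluation`) given as lists, or `seed` as a scalar.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config block(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (nm in names(user)) {
    if (nm == "seed") {
      cfg$seed <- as.integer(user$seed)
    } else {
      cfg[[nm]] <- merge_block(defaults[[nm]], user[[nm]], nm)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the blocks accepted by [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_optics <- function(cfg) do.call(optical_config, cfg$optics)

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Pair detector depths with reference depths
#'
#' Matches detections to reference localizations frame by frame by nearest
#' lateral (x, y) distance within `max_lateral_um`, each reference matching
#' at most once, closest pairs first. Used to assemble the
#' `(z_raw, z_true)` pairs a depth correction is fitted on.
#'
#' @param detections Tibble with `frame`, `x_um`, `y_um`, `z_raw` (see
#'   [add_depths()]).
#' @param reference Tibble with `frame`, `x_um`, `y_um`, `z_um`.
#' @param max_lateral_um Maximum lateral pairing distance. Default 6.
#' @return Tibble with `frame`, `z_raw`, `z_true`, `lateral_um`.
#' @export
match_depth_pairs <- function(detections, reference, max_lateral_um = 6) {
  det <- tibble::as_tibble(detections)
  ref <- tibble::as_tibble(reference)
  rows <- purrr::map(intersect(unique(det$frame), unique(ref$frame)),
                     function(f) {
    d <- det[det$frame == f, , drop = FALSE]
    r <- ref[ref$frame == f, , drop = FALSE]
    D <- sqrt(outer(d$x_um, r$x_um, `-`)^2 + outer(d$y_um, r$y_um, `-`)^2)
    pairs <- NULL
    repeat {
      k <- which.min(D)
      if (length(k) == 0 || D[k] > max_lateral_um) break
      i <- (k - 1) %% nrow(D) + 1
      j <- (k - 1) %/% nrow(D) + 1
      pairs <- rbind(pairs, c(i, j, D[k]))
      D[i, ] <- Inf
      D[, j] <- Inf
    }
    if (is.null(pairs)) return(NULL)
    tibble::tibble(frame = f, z_raw = d$z_raw[pairs[, 1]],
                   z_true = r$z_um[pairs[, 2]], lateral_um = pairs[, 3])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(frame = integer(), z_raw = double(),
                          z_true = double(), lateral_um = double())
  }
  out
}

#' Run the full pipeline on a simulated video
#'
#' Simulates a scene, renders and normalizes the video, calibrates the
#' box-size heuristic from rendered single-scatterer patterns, writes
#' ground-truth labels, runs the reference detector, fits the fourth-order
#' depth correction on a validation segment and applies it to the rest,
#' links tracks from both raw and corrected depths, and evaluates the
#' detections against the ground-truth boxes. All artifacts are written
#' under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `truth`, `cal`,
#'   `detections`, `correction`, `tracks`, `report`, `rmse` (tibble of
#'   per-track RMSE, corrected and uncorrected), `hash`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("holorun")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  optics <- config_optics(config)
  hash <- config_hash(config)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  log_stage("pipeline", "config hash %s; seed %d; R %s", hash, config$seed,
            getRversion())

  # --- simulate (test video + a validation video for the correction fit)
  sim <- config$simulation
  params_test <- motion_params(sim$n_cells, sim$n_frames, sim$speed,
                               sim$tumble_rate, sim$diffusion, sim$amplitude,
                               seed = config$seed)
  # validation split over two independent videos so the correction fit sees
  # cells across the full depth range, not one video's chance distribution
  nval <- c(ceiling(sim$n_validation_frames / 2),
            floor(sim$n_validation_frames / 2))
  truth <- simulate_scene(params_test, optics)
  truth_val_list <- lapply(1:2, function(k) {
    simulate_scene(
      motion_params(sim$n_cells, nval[k], sim$speed, sim$tumble_rate,
                    sim$diffusion, sim$amplitude,
                    seed = config$seed + 1000L * k,
                    stratified_z = TRUE),
      optics)
  })
  artifact <- if (isTRUE(sim$artifact)) {
    make_artifact(optics, seed = config$seed)
  } else NULL
  set.seed(config$seed + 2000L)
  frames <- render_video(truth, optics, noise_sd = sim$noise_sd,
                         artifact = artifact)
  frames_val_list <- lapply(truth_val_list, function(tv) {
    render_video(tv, optics, noise_sd = sim$noise_sd, artifact = artifact)
  })
  readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  log_stage("simulate", "%d test + %d validation frames, %d cells",
            length(frames), sum(nval), sim$n_cells)

  # --- preprocess
  bg <- compute_median_background(frames)
  norm <- lapply(frames, normalize_frame, background = bg)
  norm_val_list <- lapply(frames_val_list, function(fv) {
    bgv <- compute_median_background(fv)
    lapply(fv, normalize_frame, background = bgv)
  })
  write_frames_tiff(norm, file.path(out_dir, "normalized.tif"))
  log_stage("preprocess", "median background from %d frames", length(frames))

  # --- calibrate
  cal_cfg <- config$calibration
  pairs <- measure_apparent_size(optics, cal_cfg$z_grid,
                                 amplitude = sim$amplitude)
  cal <- fit_heuristic(pairs, z_range = c(cal_cfg$z_lo, cal_cfg$z_hi),
                       offset = cal_cfg$offset, radius_to_side = TRUE,
                       min_box = cal_cfg$min_box)
  write_calibration(cal, file.path(out_dir, "calibration.json"))
  log_stage("calibrate", "size(z) = %.3f z + %.2f px (n = %d)",
            cal$slope, cal$intercept, cal$n)

  # --- annotate (ground-truth boxes in darknet format)
  ann <- make_annotations(truth, cal, optics)
  write_labels(ann, file.path(out_dir, "labels"),
               frames = sort(unique(truth$frame)))
  log_stage("annotate", "%d boxes over %d frames", nrow(ann),
            length(unique(ann$frame)))

  # --- detect
  det_cfg <- config$detection
  det <- detect_video(norm, cal, optics, z_templates = det_cfg$z_templates,
                      score_threshold = det_cfg$score_threshold,
                      nms_iou = det_cfg$nms_iou,
                      support_px = det_cfg$support_px,
                      merge_px = det_cfg$merge_px,
                      box_side = det_cfg$box_side)
  det_val_list <- lapply(norm_val_list, function(nv) {
    detect_video(nv, cal, optics,
                 z_templates = det_cfg$z_templates,
                 score_threshold = det_cfg$score_threshold,
                 nms_iou = det_cfg$nms_iou,
                 support_px = det_cfg$support_px,
                 merge_px = det_cfg$merge_px,
                 box_side = det_cfg$box_side)
  })
  write_detections(det, file.path(out_dir, "detections"), optics,
                   frames = as.integer(names(norm)))
  log_stage("detect", "%d detections (test), %d (validation)",
            nrow(det), sum(vapply(det_val_list, nrow, integer(1))))

  # --- depth correction: fit on the validation videos only
  val_pairs <- dplyr::bind_rows(purrr::map2(
    det_val_list, truth_val_list, function(dv, tv) {
      match_depth_pairs(add_depths(dv, cal, optics), tv,
                        max_lateral_um = config$correction$max_lateral_um)
    }))
  correction <- fit_depth_correction(val_pairs,
                                     order = config$correction$order)
  write_correction(correction, file.path(out_dir, "correction.json"))
  log_stage("depthmap", "correction fitted on %d validation pairs, sigma %.2f um",
            correction$n, correction$sigma)

  # --- track (corrected and uncorrected depth)
  det <- add_depths(det, cal, optics, correction = correction)
  trk_cfg <- config$tracking
  tracks <- link_tracks(det, max_disp = trk_cfg$max_disp,
                        max_gap = trk_cfg$max_gap,
                        min_length = trk_cfg$min_length)
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  truth_tr <- dplyr::rename(truth, track = "cell")
  rmse_corr <- match_tracks(tracks, truth_tr)
  tracks_raw <- dplyr::mutate(tracks, z_um = .data$z_raw)
  rmse_raw <- match_tracks(tracks_raw, truth_tr)
  rmse <- dplyr::inner_join(
    dplyr::rename(rmse_corr, rmse_corrected = "rmse_um"),
    dplyr::select(dplyr::rename(rmse_raw, rmse_uncorrected = "rmse_um"),
                  "track", "rmse_uncorrected"),
    by = "track")
  readr::write_csv(rmse, file.path(out_dir, "track_rmse.csv"))
  log_stage("track", "%d tracks; mean RMSE %.2f um corrected / %.2f um raw",
            length(unique(tracks$track)),
            mean(rmse$rmse_corrected), mean(rmse$rmse_uncorrected))

  # --- evaluate detections against ground-truth boxes
  gt_boxes <- dplyr::mutate(ann,
    x_center = .data$x_center * optics$frame_width,
    y_center = .data$y_center * optics$frame_height,
    width = .data$width * optics$frame_width,
    height = .data$height * optics$frame_height)
  report <- evaluate_detections(det, gt_boxes,
                                score_threshold = config$evaluation$score_threshold)
  write_eval_report(report, file.path(out_dir, "evaluation.json"))
  log_stage("evaluate", "precision %.3f recall %.3f mAP(0.5) %.3f mAP(0.5:0.95) %.3f",
            report$precision, report$recall, report$map50, report$map50_95)

  invisible(list(truth = truth, cal = cal, detections = det,
                 correction = correction, tracks = tracks, report = report,
                 rmse = rmse, hash = hash, out_dir = out_dir))
}

#' Run one named pipeline stage
#'
#' Thin dispatcher used by the command-line interface. `"pipeline"` runs
#' everything ([run_pipeline()]); the other names run the matching exported
#' function on artifacts in `out_dir` produced by earlier stages, and raise
#' an actionable error naming the producing stage when an input is missing.
#'
#' @param name One of `"simulate"`, `"preprocess"`, `"calibrate"`,
#'   `"annotate"`, `"detect"`, `"depthmap"`, `"track"`, `"evaluate"`,
#'   `"pipeline"`.
#' @param config A [pipeline_config()].
#' @param out_dir Run directory.
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(name, config, out_dir = "holorun") {
  stopifnot(inherits(config, "pipeline_config"))
  optics <- config_optics(config)
  need <- function(path, producer) {
    if (!file.exists(path)) {
      rlang::abort(sprintf("missing input %s; run stage '%s' first",
                           path, producer))
    }
    path
  }
  switch(
    name,
    pipeline = run_pipeline(config, out_dir),
    simulate = {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      sim <- config$simulation
      truth <- simulate_scene(
        motion_params(sim$n_cells, sim$n_frames, sim$speed, sim$tumble_rate,
                      sim$diffusion, sim$amplitude, seed = config$seed),
        optics)
      artifact <- if (isTRUE(sim$artifact)) make_artifact(optics, seed = config$seed)
      set.seed(config$seed + 2000L)
      frames <- render_video(truth, optics, noise_sd = sim$noise_sd,
                             artifact = artifact)
      readr::write_csv(truth, file.path(out_dir, "truth.csv"))
      write_frames_tiff(frames, file.path(out_dir, "frames.tif"))
      log_stage("simulate", "%d frames written", length(frames))
      invisible(truth)
    },
    preprocess = {
      frames <- read_frames_tiff(need(file.path(out_dir, "frames.tif"),
                                      "simulate"))
      bg <- compute_median_background(frames)
      norm <- lapply(frames, normalize_frame, background = bg)
      write_frames_tiff(norm, file.path(out_dir, "normalized.tif"))
      log_stage("preprocess", "%d frames normalized", length(norm))
      invisible(norm)
    },
    calibrate = {
      cal_cfg <- config$calibration
      pairs <- measure_apparent_size(optics, cal_cfg$z_grid,
                                     amplitude = config$simulation$amplitude)
      cal <- fit_heuristic(pairs, z_range = c(cal_cfg$z_lo, cal_cfg$z_hi),
                           offset = cal_cfg$offset, radius_to_side = TRUE,
                           min_box = cal_cfg$min_box)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_calibration(cal, file.path(out_dir, "calibration.json"))
      log_stage("calibrate", "slope %.3f px/um", cal$slope)
      invisible(cal)
    },
    reconstruct = {
      norm <- read_frames_tiff(need(file.path(out_dir, "normalized.tif"),
                                    "preprocess"))
      rc <- config$reconstruction
      z_max <- if (is.null(rc$z_max)) optics$chamber_depth else rc$z_max
      zp <- seq(0, z_max, by = rc$dz)
      locs <- dplyr::bind_rows(purrr::map2(
        norm, as.integer(names(norm)), function(f, i) {
          locate_cells(f, optics, z_planes = zp, threshold = rc$threshold,
                       min_voxels = rc$min_voxels, smooth = rc$smooth,
                       frame_index = i, apodize_px = rc$apodize_px)
        }))
      write_localizations(locs, file.path(out_dir, "localizations.csv"))
      log_stage("reconstruct", "%d localizations over %d frames",
                nrow(locs), length(norm))
      invisible(locs)
    },
    annotate = {
      cal <- read_calibration(need(file.path(out_dir, "calibration.json"),
                                   "calibrate"))
      loc_path <- file.path(out_dir, "localizations.csv")
      locs <- if (file.exists(loc_path)) {
        read_localizations(loc_path)
      } else {
        read_localizations(need(file.path(out_dir, "truth.csv"), "simulate"))
      }
      ann <- make_annotations(locs, cal, optics)
      write_labels(ann, file.path(out_dir, "labels"),
                   frames = sort(unique(locs$frame)))
      log_stage("annotate", "%d boxes", nrow(ann))
      invisible(ann)
    },
    detect = {
      norm <- read_frames_tiff(need(file.path(out_dir, "normalized.tif"),
                                    "preprocess"))
      cal <- read_calibration(need(file.path(out_dir, "calibration.json"),
                                   "calibrate"))
      dc <- config$detection
      det <- detect_video(norm, cal, optics, z_templates = dc$z_templates,
                          score_threshold = dc$score_threshold,
                          nms_iou = dc$nms_iou, support_px = dc$support_px,
                          merge_px = dc$merge_px, box_side = dc$box_side)
      write_detections(det, file.path(out_dir, "detections"), optics,
                       frames = as.integer(names(norm)))
      log_stage("detect", "%d detections", nrow(det))
      invisible(det)
    },
    depthmap = {
      cal <- read_calibration(need(file.path(out_dir, "calibration.json"),
                                   "calibrate"))
      det <- load_detections(need(file.path(out_dir, "detections"), "detect"),
                             optics)
      det <- add_depths(det, cal, optics)
      ref_path <- file.path(out_dir, "localizations.csv")
      ref <- if (file.exists(ref_path)) read_localizations(ref_path) else {
        readr::read_csv(need(file.path(out_dir, "truth.csv"), "simulate"),
                        show_col_types = FALSE)
      }
      pairs <- match_depth_pairs(det, ref,
                                 max_lateral_um = config$correction$max_lateral_um)
      corr <- fit_depth_correction(pairs, order = config$correction$order)
      write_correction(corr, file.path(out_dir, "correction.json"))
      log_stage("depthmap", "correction fitted on %d pairs", corr$n)
      invisible(corr)
    },
    track = {
      cal <- read_calibration(need(file.path(out_dir, "calibration.json"),
                                   "calibrate"))
      det <- load_detections(need(file.path(out_dir, "detections"), "detect"),
                             optics)
      corr_path <- file.path(out_dir, "correction.json")
      corr <- if (file.exists(corr_path)) read_correction(corr_path) else NULL
      det <- add_depths(det, cal, optics, correction = corr)
      tc <- config$tracking
      tracks <- link_tracks(det, max_disp = tc$max_disp, max_gap = tc$max_gap,
                            min_length = tc$min_length)
      write_tracks(tracks, file.path(out_dir, "tracks.csv"))
      log_stage("track", "%d tracks", length(unique(tracks$track)))
      invisible(tracks)
    },
    evaluate = {
      gt <- read_labels(need(file.path(out_dir, "labels"), "annotate"))
      det_dir <- need(file.path(out_dir, "detections"), "detect")
      det <- load_detections(det_dir, optics)
      orphans <- setdiff(unique(det$frame), attr(gt, "frames"))
      if (length(orphans) > 0) {
        rlang::abort(sprintf("detection frames without label files: %s",
                             paste(orphans, collapse = ", ")))
      }
      gt_px <- dplyr::mutate(gt,
        x_center = .data$x_center * optics$frame_width,
        y_center = .data$y_center * optics$frame_height,
        width = .data$width * optics$frame_width,
        height = .data$height * optics$frame_height)
      report <- evaluate_detections(det, gt_px,
                                    score_threshold = config$evaluation$score_threshold)
      write_eval_report(report, file.path(out_dir, "evaluation.json"))
      log_stage("evaluate", "mAP(0.5) %.3f", report$map50)
      invisible(report)
    },
    rlang::abort(sprintf("unknown stage '%s'", name))
  )
}
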