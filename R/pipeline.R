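# End-to-end pipeline: simulate / calibrate / sync / track / reconstruct.
#
# Frame sequences are consumed as directories of numbered PNG frames (or
# in-memory lists of matrices, used by the test-suite). All stages are
# deterministic given the configuration and seed.

#' Frame source abstraction
#'
#' @param x Directory containing numbered PNG frames, or a list of
#'   grayscale matrices (0-255).
#' @return List with `n` and `get(i)` returning frame i as a matrix (0-255).
#' @export
frame_source <- function(x) {
  if (is.character(x)) {
    if (!dir.exists(x)) stop(sprintf("frame directory does not exist: %s", x))
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop(sprintf("no PNG frames found in %s", x))
    list(n = length(files), get = function(i) {
      img <- png::readPNG(files[i])
      if (length(dim(img)) == 3) img <- img[, , 1]
      img * 255
    })
  } else if (is.list(x)) {
    list(n = length(x), get = function(i) x[[i]])
  } else stop("frame source must be a directory path or a list of matrices")
}

#' Tracking-stage options
#'
#' Per-frame segmentation and detection parameters. The defaults suit
#' sequences on the generator's compressed timebase (photoperiod 40:20
#' frames); recordings at one frame per minute with a real 16:8-hour cycle
#' correspond to proportionally slower adaptation (learning_rate ~ 0.01,
#' cooldown ~ 30 frames).
#'
#' @param learning_rate MOG per-frame update fraction.
#' @param max_components,background_threshold,var_threshold,var_floor,init_var
#'   See [mog_model()].
#' @param min_contour_area Contours below this pixel count are noise.
#' @param close_radius Morphological-closing radius on the raw mask.
#' @param lighting_change_area Foreground area (px) declaring a lighting
#'   change; `NULL` = 25% of the image area.
#' @param lighting_change_est_time Cooldown frames between lighting changes.
#' @param epipolar_threshold Side-view fragment selection distance (px).
#' @param max_candidates Candidate cap per frame per view.
#' @return A list of class `track_options`.
#' @export
track_options <- function(learning_rate = 0.18, max_components = 5L,
                          background_threshold = 0.9, var_threshold = 16,
                          var_floor = 1, init_var = 4,
                          min_contour_area = 6, close_radius = 3L,
                          lighting_change_area = NULL,
                          lighting_change_est_time = 8L,
                          epipolar_threshold = 8, max_candidates = 5L) {
  structure(as.list(environment()), class = "track_options")
}

sequence_luminance <- function(src) {
  vapply(seq_len(src$n), function(i) mean(src$get(i)), numeric(1))
}

#' Synchronize two sequences from their photoperiod signal
#'
#' @param top,side Frame sources (directories or lists).
#' @return A [sync_result()].
#' @export
run_sync <- function(top, side) {
  st <- frame_source(top); ss <- frame_source(side)
  estimate_offset(sequence_luminance(st), sequence_luminance(ss))
}

# one segmentation+detection pass over a view
track_view <- function(src, base, opts, extractor) {
  probe <- src$get(1)
  model <- mog_model(ncol(probe), nrow(probe),
                     max_components = opts$max_components,
                     learning_rate = opts$learning_rate,
                     background_threshold = opts$background_threshold,
                     var_threshold = opts$var_threshold,
                     var_floor = opts$var_floor, init_var = opts$init_var)
  area_thr <- if (is.null(opts$lighting_change_area))
    0.25 * ncol(probe) * nrow(probe) else opts$lighting_change_area
  lcfg <- lighting_config(area_thr, opts$lighting_change_est_time)
  track <- new_track(seq_len(src$n))
  fslc <- Inf
  prev <- NULL
  for (i in seq_len(src$n)) {
    seg <- segment_frame(model, src$get(i), lcfg, fslc, opts$min_contour_area,
                         opts$close_radius)
    fslc <- if (seg$lighting_change) 0 else fslc + 1
    cand <- extractor(seg$contours, i)
    sel <- select_tip(cand, prev)
    if (!is.null(sel)) {
      track$u[i] <- sel$pixel[["u"]]; track$v[i] <- sel$pixel[["v"]]
      track$label[i] <- sel$label
      prev <- sel$pixel
    }
  }
  interpolate_gaps(track)
}

#' Track the plant tip in both views of a synchronized sequence pair
#'
#' Runs the full per-view pipeline: photoperiod sync, mixture-of-Gaussians
#' segmentation with lighting-change resets, candidate extraction (epipolar
#' guided in the side view), temporal selection, gap interpolation and
#' manual-correction merging.
#'
#' @param top,side Frame sources (directories or lists of matrices).
#' @param rig A `stereo_rig` (used for the epipolar guidance; may be `NULL`
#'   to disable it).
#' @param base_top,base_side [base_anchor()]s marking the pot base.
#' @param opts A [track_options()].
#' @param corrections Optional corrections data frame (frame_id, view, u, v).
#' @param sync Optional precomputed [sync_result()]; computed when missing.
#' @return List with `track_top`, `track_side`, `sync`, `summary`.
#' @export
run_track <- function(top, side, rig, base_top, base_side,
                      opts = track_options(), corrections = NULL,
                      sync = NULL) {
  st <- frame_source(top); ss <- frame_source(side)
  if (is.null(sync))
    sync <- estimate_offset(sequence_luminance(st), sequence_luminance(ss))
  track_top <- track_view(st, base_top, opts, function(contours, i)
    extract_candidates_top(contours, base_top, opts$max_candidates, i))
  track_side <- track_view(ss, base_side, opts, function(contours, i) {
    line <- NULL
    if (!is.null(rig)) {
      j <- i - sync$offset_frames  # aligned top frame
      k <- match(j, track_top$frame_id)
      if (!is.na(k))
        line <- tryCatch(
          epipolar_line(rig$F, c(track_top$u[k], track_top$v[k])),
          error = function(e) NULL)
    }
    extract_candidates_side(contours, base_side, line,
                            opts$epipolar_threshold, opts$max_candidates, i)
  })
  if (!is.null(corrections)) {
    track_top <- apply_corrections(track_top,
                                   corrections[corrections$view == "top", ])
    track_side <- apply_corrections(track_side,
                                    corrections[corrections$view == "side", ])
  }
  list(track_top = track_top, track_side = track_side, sync = sync,
       summary = detection_summary(track_top, track_side))
}

#' Generate a synthetic dataset on disk
#'
#' Thin wrapper over [generate_sequence_pair()] and
#' [render_calibration_set()]: writes frames, truth manifest, camera truth
#' and (optionally) calibration images under `out_dir`.
#'
#' @param out_dir Output directory (created).
#' @param n_frames,offset_frames Sequence shape.
#' @param scene A [scene_config()].
#' @param trajectory Parameters forwarded to [make_trajectory()].
#' @return The [generate_sequence_pair()] result, invisibly.
#' @export
run_simulate <- function(out_dir, n_frames = 300L, offset_frames = 7L,
                         scene = scene_config(), trajectory = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- generate_sequence_pair(scene, n_frames, offset_frames,
                                dir = out_dir, trajectory = trajectory)
  invisible(res)
}

#' Calibrate both cameras and the stereo rig from board observation sets
#'
#' @param obs_top,obs_side Lists of `board_observation`s (or rendered images
#'   to be passed through [detect_chessboard()] first by the caller).
#' @param obs_stereo List of simultaneous pairs `list(top=, side=)`.
#' @param image_size c(width, height).
#' @return List with `rig`, `report` (six reprojection-error columns:
#'   mean/stdev for top camera, side camera and stereo system), `cal_top`,
#'   `cal_side`.
#' @export
run_calibrate <- function(obs_top, obs_side, obs_stereo, image_size) {
  cal_top <- calibrate_camera(obs_top, image_size)
  cal_side <- calibrate_camera(obs_side, image_size)
  cam_top <- camera_model(cal_top$intrinsics, cal_top$distortion)
  cam_side <- camera_model(cal_side$intrinsics, cal_side$distortion)
  st <- calibrate_stereo(obs_stereo, cam_top, cam_side)
  list(rig = st$rig, report = st$report, cal_top = cal_top, cal_side = cal_side)
}

#' Reconstruct and export the 3D trajectory
#'
#' @param rig A `stereo_rig`.
#' @param tracks Result of [run_track()].
#' @param flag_threshold Mean reprojection error (px) flagging a frame.
#' @param out_dir Optional directory for trajectory and report CSVs.
#' @return [reconstruct_trajectory()] result.
#' @export
run_reconstruct <- function(rig, tracks, flag_threshold = 10, out_dir = NULL) {
  rec <- reconstruct_trajectory(rig, tracks$track_top, tracks$track_side,
                                tracks$sync, flag_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_csv(rec$points, file.path(out_dir, "trajectory.csv"))
    rep <- rec$report
    utils::write.csv(
      data.frame(view = c("top", "side"),
                 mean_re = c(rep$mean_re_top, rep$mean_re_side),
                 stdev_re = c(rep$stdev_re_top, rep$stdev_re_side),
                 total_points = rep$total_points,
                 points_gt_thresh = rep$n_flagged),
      file.path(out_dir, "reprojection_report.csv"), row.names = FALSE)
  }
  rec
}
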