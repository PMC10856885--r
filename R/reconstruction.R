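# Two-view triangulation, reprojection-error auditing and study summaries.

#' Triangulate a 3D point from a top/side pixel pair
#'
#' Both pixels are undistorted to normalized coordinates; the point is the
#' least-squares solution of the two-ray linear (DLT) system, refined by one
#' Gauss-Newton step on the summed squared pixel reprojection error.
#'
#' @param rig A `stereo_rig`.
#' @param p_top,p_side Length-2 pixels (u, v) in each view.
#' @param min_ray_angle_deg Rays closer to parallel than this are rejected
#'   as ill-conditioned.
#' @return Length-3 world point (cm).
#' @export
triangulate <- function(rig, p_top, p_side, min_ray_angle_deg = 0.5) {
  cams <- list(rig$top, rig$side)
  pix <- list(p_top, p_side)
  xy <- lapply(seq_len(2), function(i) as.numeric(pixel_to_normalized(cams[[i]], pix[[i]])))
  dirs <- lapply(seq_len(2), function(i)
    as.numeric(crossprod(cams[[i]]$pose$R, c(xy[[i]], 1))))
  cosang <- sum(dirs[[1]] * dirs[[2]]) /
    sqrt(sum(dirs[[1]]^2) * sum(dirs[[2]]^2))
  ang <- acos(min(1, max(-1, cosang))) * 180 / pi
  if (ang < min_ray_angle_deg)
    stop(sprintf("ill-conditioned triangulation: ray angle %.3f deg", ang))
  A <- matrix(0, 4, 3); b <- numeric(4)
  for (i in seq_len(2)) {
    R <- cams[[i]]$pose$R; t <- cams[[i]]$pose$t
    A[2 * i - 1, ] <- xy[[i]][1] * R[3, ] - R[1, ]
    A[2 * i, ] <- xy[[i]][2] * R[3, ] - R[2, ]
    b[2 * i - 1] <- t[1] - xy[[i]][1] * t[3]
    b[2 * i] <- t[2] - xy[[i]][2] * t[3]
  }
  P <- as.numeric(qr.solve(A, b))
  # one Gauss-Newton step on pixel reprojection residuals
  resid <- function(X) {
    r <- tryCatch(c(project_points(cams[[1]], X) - rbind(p_top[1:2]),
                    project_points(cams[[2]], X) - rbind(p_side[1:2])),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    as.numeric(r)
  }
  r0 <- resid(P)
  if (!is.null(r0)) {
    eps <- 1e-5
    J <- vapply(1:3, function(j) {
      Pj <- P; Pj[j] <- Pj[j] + eps
      rj <- resid(Pj)
      if (is.null(rj)) r0 else (rj - r0) / eps
    }, numeric(4))
    step <- tryCatch(qr.solve(J, -r0), error = function(e) rep(0, 3))
    P1 <- P + as.numeric(step)
    r1 <- resid(P1)
    if (!is.null(r1) && sum(r1^2) < sum(r0^2)) P <- P1
  }
  P
}

#' Per-view reprojection error of a reconstructed point
#'
#' @param rig A `stereo_rig`.
#' @param xyz Length-3 world point (cm), in front of both cameras.
#' @param p_top,p_side Observed pixels.
#' @return Named vector c(re_top, re_side, re_mean) in pixels.
#' @export
reprojection_error <- function(rig, xyz, p_top, p_side) {
  rt <- sqrt(sum((project_points(rig$top, xyz) - rbind(p_top[1:2]))^2))
  rs <- sqrt(sum((project_points(rig$side, xyz) - rbind(p_side[1:2]))^2))
  c(re_top = rt, re_side = rs, re_mean = (rt + rs) / 2)
}

#' Reconstruct the 3D tip trajectory from paired tracks
#'
#' Aligns the side track to the top track using the photoperiod offset
#' (side frame = top frame + offset), triangulates every aligned pair,
#' computes per-frame reprojection errors and flags frames whose mean error
#' exceeds `flag_threshold`.
#'
#' @param rig A `stereo_rig`.
#' @param track_top,track_side Gap-free track data frames.
#' @param sync A [sync_result()] (or an integer offset).
#' @param flag_threshold Mean reprojection error (px) above which a frame is
#'   flagged.
#' @return List with `points` (data frame: frame_id, X_cm, Y_cm, Z_cm,
#'   u_top, v_top, u_side, v_side, label_top, label_side, re_top_px,
#'   re_side_px, flagged) and `report` (list with per-view mean/stdev
#'   reprojection error, total_points, n_flagged, per-frame error series).
#' @export
reconstruct_trajectory <- function(rig, track_top, track_side, sync = 0L,
                                   flag_threshold = 10) {
  offset <- if (inherits(sync, "sync_result")) sync$offset_frames else as.integer(sync)
  side_ids <- track_top$frame_id + offset
  keep <- side_ids %in% track_side$frame_id
  if (!any(keep)) stop("empty reconstruction: no overlapping frames after offset")
  top <- track_top[keep, ]
  side <- track_side[match(side_ids[keep], track_side$frame_id), ]
  n <- nrow(top)
  out <- data.frame(frame_id = top$frame_id,
                    X_cm = NA_real_, Y_cm = NA_real_, Z_cm = NA_real_,
                    u_top = top$u, v_top = top$v,
                    u_side = side$u, v_side = side$v,
                    label_top = top$label, label_side = side$label,
                    re_top_px = NA_real_, re_side_px = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    P <- triangulate(rig, c(top$u[i], top$v[i]), c(side$u[i], side$v[i]))
    re <- reprojection_error(rig, P, c(top$u[i], top$v[i]),
                             c(side$u[i], side$v[i]))
    out$X_cm[i] <- P[1]; out$Y_cm[i] <- P[2]; out$Z_cm[i] <- P[3]
    out$re_top_px[i] <- re[["re_top"]]
    out$re_side_px[i] <- re[["re_side"]]
    out$flagged[i] <- re[["re_mean"]] > flag_threshold
  }
  report <- list(
    mean_re_top = mean(out$re_top_px), stdev_re_top = stats::sd(out$re_top_px),
    mean_re_side = mean(out$re_side_px), stdev_re_side = stats::sd(out$re_side_px),
    total_points = n, n_flagged = sum(out$flagged),
    flag_threshold = flag_threshold,
    re_top_series = out$re_top_px, re_side_series = out$re_side_px)
  list(points = out, report = report)
}

#' Write a trajectory CSV
#' @param trajectory `points` data frame from [reconstruct_trajectory()].
#' @param path Output path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

# ---- study-level summaries --------------------------------------------------

#' Combine per-video reprojection and detection tables into study totals
#'
#' The overall mean reprojection error is the unweighted mean of the
#' per-video per-view mean errors (a point-weighted average differs in the
#' second decimal); the high-error fraction and manual fraction are
#' count-weighted over all points/frames.
#'
#' @param reprojection Data frame with one row per video+view: columns
#'   `mean_re`, `total_points`, `points_gt_thresh`.
#' @param detections Optional data frame with per-video+view detection-type
#'   counts (columns automatic, manual, estimated, interpolated).
#' @param image_width Image width in px used to express the overall error as
#'   a percentage of image width.
#' @return List with `overall_mean_re_px`, `high_error_pct`,
#'   `mean_re_pct_of_width`, and (when `detections` given) `manual_pct` and
#'   `automatic_pct`.
#' @export
summarize_tables <- function(reprojection, detections = NULL, image_width = 1280) {
  stopifnot(nrow(reprojection) >= 1)
  out <- list(
    overall_mean_re_px = mean(reprojection$mean_re),
    high_error_pct = 100 * sum(reprojection$points_gt_thresh) /
      sum(reprojection$total_points),
    mean_re_pct_of_width = 100 * mean(reprojection$mean_re) / image_width)
  if (!is.null(detections)) {
    counts <- detections[, c("automatic", "manual", "estimated", "interpolated")]
    total <- sum(counts)
    out$manual_pct <- 100 * sum(counts$manual) / total
    out$automatic_pct <- 100 * (total - sum(counts$manual)) / total
    out$range_totals <- rowSums(counts)
  }
  out
}

#' Bundled summary tables of an example three-pair tracking study
#'
#' Plain-text copies of the calibration, detection-type and
#' reprojection-error summary tables of an example study of three stereo
#' video pairs of climbing beans (with/without a support pole), used to
#' exercise the study-level summary computations.
#'
#' @return List of data frames `calibration`, `detections`, `reprojection`.
#' @export
example_study_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "stereonut", mustWork = TRUE)
  list(calibration = utils::read.csv(p("example_calibration_errors.csv")),
       detections = utils::read.csv(p("example_detection_counts.csv")),
       reprojection = utils::read.csv(p("example_reprojection_summary.csv")))
}
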