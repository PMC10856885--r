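# Single-camera and stereo calibration from chessboard observations.
#
# Single-camera path: per-view homographies -> closed-form intrinsic
# initialization (Zhang's method) -> per-view extrinsics -> joint
# Levenberg-Marquardt refinement of intrinsics, distortion and all poses,
# minimizing total squared reprojection error. Stereo path: fixed-intrinsics
# pose estimation (PnP) per camera per board pair, per-pair relative poses,
# fused by quaternion averaging.

# ---- reports ----------------------------------------------------------------

calibration_report <- function(errors, per_view_re) {
  structure(list(mean_re = mean(errors), stdev_re = stats::sd(errors),
                 per_view_re = per_view_re, n_points = length(errors)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration_report: mean RE %.5f px, stdev %.5f px, %d points, %d views\n",
              x$mean_re, x$stdev_re, x$n_points, length(x$per_view_re)))
  invisible(x)
}

# per-point Euclidean reprojection errors of one board view
view_reproj_errors <- function(intr, dist, pose, obs) {
  cam <- camera_model(intr, dist, pose)
  pred <- project_points(cam, obs$object_points)
  sqrt(rowSums((pred - obs$image_points)^2))
}

# ---- Zhang initialization ---------------------------------------------------

zhang_intrinsics_init <- function(homographies, image_size) {
  vrow <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(homographies, function(H) {
    rbind(vrow(H, 1, 2), vrow(H, 1, 1) - vrow(H, 2, 2))
  }))
  b <- svd(V, nu = 0)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  v0 <- (B12 * B13 - B11 * B23) / den
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  fx2 <- lam / B11; fy2 <- lam * B11 / den
  if (fx2 <= 0 || fy2 <= 0) stop("under-constrained calibration: degenerate board poses")
  fx <- sqrt(fx2); fy <- sqrt(fy2)
  u0 <- -B13 * fx^2 / lam
  intrinsics(fx, fy,
             min(max(u0, 0), image_size[1] - 1),
             min(max(v0, 0), image_size[2] - 1),
             image_size[1], image_size[2])
}

# extrinsics of a plane homography given the intrinsic matrix
extrinsics_from_homography <- function(H, A) {
  Ai <- solve(A)
  h1 <- Ai %*% H[, 1]; h2 <- Ai %*% H[, 2]; h3 <- Ai %*% H[, 3]
  lam <- 1 / sqrt(sum(h1^2))
  if (lam * h3[3] < 0) lam <- -lam  # board in front of the camera
  r1 <- lam * h1; r2 <- lam * h2
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R0 <- cbind(r1, r2, r3)
  s <- svd(R0)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  pose(R, as.numeric(lam * h3))
}

# ---- single-camera calibration ----------------------------------------------

#' Calibrate a camera from chessboard observations
#'
#' Estimates intrinsics, lens distortion and one pose per view by minimizing
#' the total squared reprojection error over all board corners.
#'
#' @param observations List of `board_observation`s (at least 3, with
#'   distinct board poses).
#' @param image_size c(width, height) in pixels.
#' @param fix_k3 Keep the sixth-order radial coefficient at zero. Defaults
#'   to `TRUE` unless 15 or more views are provided; estimating k3 from few
#'   boards is unstable with wide-angle optics.
#' @return List with `intrinsics`, `distortion`, `poses` (per view),
#'   and `report` (a `calibration_report`).
#' @export
calibrate_camera <- function(observations, image_size,
                             fix_k3 = length(observations) < 15) {
  observations <- Filter(Negate(is.null), observations)
  if (length(observations) < 3)
    stop("under-constrained calibration: need at least 3 board views")
  Hs <- lapply(observations, function(o)
    homography_dlt(o$object_points[, 1:2], o$image_points))
  intr0 <- zhang_intrinsics_init(Hs, image_size)
  A0 <- intrinsic_matrix(intr0)
  poses0 <- lapply(Hs, extrinsics_from_homography, A = A0)

  n_dist <- if (fix_k3) 4L else 5L
  pack <- function(intr, dist, poses) {
    d <- c(dist$k1, dist$k2, dist$p1, dist$p2, if (!fix_k3) dist$k3)
    c(intr$fx, intr$fy, intr$cx, intr$cy, d,
      unlist(lapply(poses, function(p) c(matrix_to_rodrigues(p$R), p$t))))
  }
  unpack <- function(par) {
    intr <- intrinsics(par[1], par[2],
                       min(max(par[3], 0), image_size[1] - 1e-9),
                       min(max(par[4], 0), image_size[2] - 1e-9),
                       image_size[1], image_size[2])
    dist <- distortion(k1 = par[5], k2 = par[6], p1 = par[7], p2 = par[8],
                       k3 = if (fix_k3) 0 else par[9])
    off <- 4L + n_dist
    poses <- lapply(seq_along(observations), function(i) {
      q <- par[off + (i - 1) * 6 + 1:6]
      pose(rodrigues_to_matrix(q[1:3]), q[4:6])
    })
    list(intr = intr, dist = dist, poses = poses)
  }
  resid_fn <- function(par) {
    st <- tryCatch(unpack(par), error = function(e) NULL)
    if (is.null(st)) return(rep(1e6, 2))
    unlist(lapply(seq_along(observations), function(i) {
      cam <- camera_model(st$intr, st$dist, st$poses[[i]])
      pred <- tryCatch(project_points(cam, observations[[i]]$object_points),
                       error = function(e) NULL)
      if (is.null(pred)) return(rep(1e6, 2 * nrow(observations[[i]]$object_points)))
      as.numeric(pred - observations[[i]]$image_points)
    }))
  }
  p0 <- pack(intr0, distortion(), poses0)
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  st <- unpack(fit$par)
  errs <- lapply(seq_along(observations), function(i)
    view_reproj_errors(st$intr, st$dist, st$poses[[i]], observations[[i]]))
  list(intrinsics = st$intr, distortion = st$dist, poses = st$poses,
       report = calibration_report(unlist(errs), vapply(errs, mean, numeric(1))))
}

# ---- PnP --------------------------------------------------------------------

#' Estimate the pose of a calibrated camera from one board view
#'
#' Homography-based initialization in undistorted normalized coordinates,
#' refined by Levenberg-Marquardt on the full projection model.
#'
#' @param obs A `board_observation`.
#' @param intr,dist Calibrated [intrinsics()] and [distortion()].
#' @return A [pose()] (board frame to camera frame).
#' @export
solve_pnp <- function(obs, intr, dist) {
  cam0 <- camera_model(intr, dist)
  xy <- pixel_to_normalized(cam0, obs$image_points)
  H <- homography_dlt(obs$object_points[, 1:2], xy)
  p0 <- extrinsics_from_homography(H, diag(3))
  par0 <- c(matrix_to_rodrigues(p0$R), p0$t)
  resid_fn <- function(par) {
    cam <- tryCatch(
      camera_model(intr, dist, pose(rodrigues_to_matrix(par[1:3]), par[4:6])),
      error = function(e) NULL)
    if (is.null(cam)) return(rep(1e6, 2 * nrow(obs$object_points)))
    pred <- tryCatch(project_points(cam, obs$object_points), error = function(e) NULL)
    if (is.null(pred)) return(rep(1e6, 2 * nrow(obs$object_points)))
    as.numeric(pred - obs$image_points)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-14, ptol = 1e-14))
  pose(rodrigues_to_matrix(fit$par[1:3]), fit$par[4:6])
}

# ---- relative pose and two-view matrices ------------------------------------

#' Relative pose between two cameras seeing the same frame
#'
#' Given world-to-camera poses (R1, t1) and (R2, t2), returns (R, t) with
#' R2 = R R1 and t2 = R t1 + t.
#'
#' @param pose1,pose2 [pose()] objects.
#' @return List with `R_rel` (3x3) and `t_rel` (length 3, cm).
#' @export
relative_pose <- function(pose1, pose2) {
  R_rel <- pose2$R %*% t(pose1$R)
  list(R_rel = R_rel, t_rel = as.numeric(pose2$t - R_rel %*% pose1$t))
}

#' Essential matrix of a relative pose
#'
#' E = [t]x R, with [t]x the skew-symmetric cross-product matrix.
#'
#' @param R_rel 3x3 relative rotation.
#' @param t_rel Relative translation (length 3); must be nonzero.
#' @return 3x3 essential matrix (rank 2).
#' @export
essential_matrix <- function(R_rel, t_rel) {
  if (sqrt(sum(t_rel^2)) <= 0)
    stop("degenerate rig: zero baseline has no essential matrix")
  skew3(t_rel) %*% R_rel
}

#' Fundamental matrix from the essential matrix and the two intrinsics
#'
#' F = A_side^-T E A_top^-1, oriented so that for a pixel p in the top view
#' the homogeneous line F p is its epipolar line in the side view.
#'
#' @param E Essential matrix of the top-to-side relative pose.
#' @param A_top,A_side [intrinsics()] of the two cameras (or 3x3 matrices).
#' @return 3x3 fundamental matrix (rank 2).
#' @export
fundamental_matrix <- function(E, A_top, A_side) {
  if (inherits(A_top, "intrinsics")) A_top <- intrinsic_matrix(A_top)
  if (inherits(A_side, "intrinsics")) A_side <- intrinsic_matrix(A_side)
  t(solve(A_side)) %*% E %*% solve(A_top)
}

# ---- quaternion helpers (rotation averaging) --------------------------------

matrix_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# chordal-mean rotation: principal eigenvector of the sum of qq'
average_rotations <- function(Rs) {
  qs <- lapply(Rs, matrix_to_quat)
  q0 <- qs[[1]]
  M <- matrix(0, 4, 4)
  for (q in qs) {
    if (sum(q * q0) < 0) q <- -q
    M <- M + tcrossprod(q)
  }
  quat_to_matrix(eigen(M, symmetric = TRUE)$vectors[, 1])
}

rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

# ---- stereo calibration ------------------------------------------------------

#' Assemble a stereo rig
#'
#' @param top,side Calibrated [camera_model()]s (poses expressed in a common
#'   world frame).
#' @param R_rel,t_rel Pose of the side camera relative to the top camera.
#' @return An object of class `stereo_rig` with essential and fundamental
#'   matrices attached.
#' @export
stereo_rig <- function(top, side, R_rel, t_rel) {
  E <- essential_matrix(R_rel, t_rel)
  F <- fundamental_matrix(E, top$intrinsics, side$intrinsics)
  sv <- svd(E)$d
  if (sv[3] > 1e-6 * sv[1]) stop("essential matrix is not rank 2")
  if (abs(det(F)) > 1e-6 * norm(F, "F"))
    stop("fundamental matrix is not rank deficient")
  structure(list(top = top, side = side, R_rel = R_rel,
                 t_rel = as.numeric(t_rel), E = E, F = F),
            class = "stereo_rig")
}

#' Calibrate the stereo rig from simultaneous board pairs
#'
#' Each pair gives one relative pose between the cameras (via per-camera
#' PnP); pairs are fused by quaternion rotation averaging and translation
#' averaging. The world frame is anchored at the first pair's board origin.
#' The report's per-camera errors use each camera's own board pose; the
#' stereo errors reproject the side view through the fused rig, so they
#' include any rig inconsistency.
#'
#' @param obs_pairs List of `list(top = board_observation, side =
#'   board_observation)` captured simultaneously.
#' @param cam_top,cam_side Individually calibrated [camera_model()]s.
#' @param max_rotation_spread_deg Largest tolerated angular deviation of a
#'   per-pair relative rotation from the fused rotation (degrees).
#' @return List with `rig` (a `stereo_rig`) and `report` (a data frame with
#'   mean/stdev reprojection error for top camera, side camera and the
#'   stereo system) plus `reports` holding the three `calibration_report`s.
#' @export
calibrate_stereo <- function(obs_pairs, cam_top, cam_side,
                             max_rotation_spread_deg = 5) {
  if (length(obs_pairs) < 1) stop("need at least one simultaneous board pair")
  poses_top <- lapply(obs_pairs, function(p)
    solve_pnp(p$top, cam_top$intrinsics, cam_top$distortion))
  poses_side <- lapply(obs_pairs, function(p)
    solve_pnp(p$side, cam_side$intrinsics, cam_side$distortion))
  rels <- Map(relative_pose, poses_top, poses_side)
  R_rel <- average_rotations(lapply(rels, `[[`, "R_rel"))
  spread <- vapply(rels, function(r)
    rotation_angle_deg(r$R_rel %*% t(R_rel)), numeric(1))
  if (max(spread) > max_rotation_spread_deg)
    stop(sprintf("unstable stereo calibration: rotation spread %.2f deg", max(spread)))
  t_rel <- colMeans(do.call(rbind, lapply(rels, `[[`, "t_rel")))

  top_cam <- camera_model(cam_top$intrinsics, cam_top$distortion, poses_top[[1]])
  side_pose <- pose(R_rel %*% poses_top[[1]]$R,
                    as.numeric(R_rel %*% poses_top[[1]]$t + t_rel))
  side_cam <- camera_model(cam_side$intrinsics, cam_side$distortion, side_pose)
  rig <- stereo_rig(top_cam, side_cam, R_rel, t_rel)

  err_top <- unlist(lapply(seq_along(obs_pairs), function(i)
    view_reproj_errors(cam_top$intrinsics, cam_top$distortion,
                       poses_top[[i]], obs_pairs[[i]]$top)))
  err_side <- unlist(lapply(seq_along(obs_pairs), function(i)
    view_reproj_errors(cam_side$intrinsics, cam_side$distortion,
                       poses_side[[i]], obs_pairs[[i]]$side)))
  err_stereo <- unlist(lapply(seq_along(obs_pairs), function(i) {
    composed <- pose(R_rel %*% poses_top[[i]]$R,
                     as.numeric(R_rel %*% poses_top[[i]]$t + t_rel))
    c(view_reproj_errors(cam_top$intrinsics, cam_top$distortion,
                         poses_top[[i]], obs_pairs[[i]]$top),
      view_reproj_errors(cam_side$intrinsics, cam_side$distortion,
                         composed, obs_pairs[[i]]$side))
  }))
  report <- data.frame(
    mean_re_top = mean(err_top), stdev_re_top = stats::sd(err_top),
    mean_re_side = mean(err_side), stdev_re_side = stats::sd(err_side),
    mean_re_stereo = mean(err_stereo), stdev_re_stereo = stats::sd(err_stereo))
  list(rig = rig, report = report,
       reports = list(top = calibration_report(err_top, NULL),
                      side = calibration_report(err_side, NULL),
                      stereo = calibration_report(err_stereo, NULL)))
}

# ---- rig serialization ------------------------------------------------------

#' Write a stereo rig to YAML
#' @param rig A `stereo_rig`.
#' @param path Output file path.
#' @export
write_rig_yaml <- function(rig, path) {
  x <- list(top = camera_to_list(rig$top), side = camera_to_list(rig$side),
            R_rel = as.numeric(t(rig$R_rel)), t_rel = rig$t_rel,
            E = as.numeric(t(rig$E)), F = as.numeric(t(rig$F)))
  writeLines(yaml::as.yaml(x, precision = 17L), path)
  invisible(path)
}

#' Read a stereo rig written by [write_rig_yaml()]
#' @param path Input file path.
#' @return A `stereo_rig`.
#' @export
read_rig_yaml <- function(path) {
  x <- yaml::yaml.load_file(path)
  stereo_rig(camera_from_list(x$top), camera_from_list(x$side),
             t(matrix(as.numeric(x$R_rel), 3, 3)), as.numeric(x$t_rel))
}
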