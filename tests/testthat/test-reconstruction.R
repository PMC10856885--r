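truth_rig <- function(cfg = scene_config()) {
  cams <- true_cameras(cfg)
  rel <- relative_pose(cams$top$pose, cams$side$pose)
  list(rig = stereo_rig(cams$top, cams$side, rel$R_rel, rel$t_rel),
       cams = cams, cfg = cfg)
}

test_that("triangulation inverts noiseless projection exactly", {
  tw <- truth_rig()
  pts <- make_trajectory(tw$cfg, 30)
  for (i in seq_len(nrow(pts))) {
    P <- triangulate(tw$rig,
                     project_points(tw$cams$top, pts[i, ]),
                     project_points(tw$cams$side, pts[i, ]))
    expect_lt(sqrt(sum((P - pts[i, ])^2)), 1e-6)
  }
})

test_that("near-parallel rays are rejected", {
  cfg <- scene_config()
  intr <- true_cameras(cfg)$top$intrinsics
  # two cameras almost co-located looking the same way: tiny baseline
  c1 <- camera_model(intr, pose = pose(diag(3), c(0, 0, 0)))
  c2 <- camera_model(intr, pose = pose(diag(3), c(0.01, 0, 0)))
  rel <- relative_pose(c1$pose, c2$pose)
  rig <- stereo_rig(c1, c2, rel$R_rel, rel$t_rel)
  P <- c(0, 0, 200)
  expect_error(triangulate(rig, project_points(c1, P), project_points(c2, P)),
               "ill-conditioned")
})

test_that("DLT+refinement agrees with a lattice-and-refine oracle", {
  set.seed(71)
  tw <- truth_rig()
  cost <- function(X, pt, ps) {
    sum((project_points(tw$cams$top, X) - rbind(pt))^2) +
      sum((project_points(tw$cams$side, X) - rbind(ps))^2)
  }
  for (trial in 1:4) {
    P <- c(runif(1, -15, 15), runif(1, -15, 15), runif(1, 35, 70))
    pt <- project_points(tw$cams$top, P) + rnorm(2, 0, 1)
    ps <- project_points(tw$cams$side, P) + rnorm(2, 0, 1)
    est <- triangulate(tw$rig, pt, ps)
    # brute force: coarse lattice around the true point, then simplex refine
    g <- as.matrix(expand.grid(x = seq(P[1] - 3, P[1] + 3, 0.5),
                               y = seq(P[2] - 3, P[2] + 3, 0.5),
                               z = seq(P[3] - 3, P[3] + 3, 0.5)))
    costs <- apply(g, 1, cost, pt = pt, ps = ps)
    ref <- optim(g[which.min(costs), ], cost, pt = pt, ps = ps,
                 control = list(reltol = 1e-14, maxit = 2000))
    expect_lt(sqrt(sum((est - ref$par)^2)), 0.02)
    expect_lte(cost(est, pt, ps), ref$value * (1 + 1e-6) + 1e-9)
  }
})

test_that("reprojection errors match the per-view distance formula", {
  tw <- truth_rig()
  P <- c(5, -3, 50)
  pt <- project_points(tw$cams$top, P); ps <- project_points(tw$cams$side, P)
  re0 <- reprojection_error(tw$rig, triangulate(tw$rig, pt, ps), pt, ps)
  expect_lt(max(re0), 1e-6)
  # shift one observation by 12 px: that view's error is 12
  ps_bad <- ps + c(12, 0)
  re <- reprojection_error(tw$rig, P, pt, ps_bad)
  expect_equal(unname(re[["re_side"]]), 12, tolerance = 1e-9)
  expect_equal(unname(re[["re_top"]]), 0, tolerance = 1e-9)
  expect_equal(unname(re[["re_mean"]]), 6, tolerance = 1e-9)
  # independent hand computation
  proj <- project_points(tw$rig$side, P)
  expect_equal(unname(re[["re_side"]]),
               sqrt(sum((proj - rbind(ps_bad[1:2]))^2)), tolerance = 1e-12)
})

test_that("trajectory reconstruction aggregates errors and flags correctly", {
  tw <- truth_rig()
  n <- 60
  pts <- make_trajectory(tw$cfg, n)
  pt <- project_points(tw$cams$top, pts)
  ps <- project_points(tw$cams$side, pts)
  track_top <- data.frame(frame_id = 1:n, u = pt[, 1], v = pt[, 2],
                          label = "automatic")
  track_side <- data.frame(frame_id = 1:n, u = ps[, 1], v = ps[, 2],
                           label = "automatic")
  # corrupt two side frames so they flag
  track_side$u[c(10, 20)] <- track_side$u[c(10, 20)] + 40
  rec <- reconstruct_trajectory(tw$rig, track_top, track_side, 0L,
                                flag_threshold = 10)
  expect_equal(rec$report$total_points, n)
  expect_equal(rec$report$n_flagged, 2)
  expect_true(all(rec$points$flagged[c(10, 20)]))
  err3d <- sqrt(rowSums((as.matrix(rec$points[, c("X_cm", "Y_cm", "Z_cm")]) -
                           pts)^2))
  expect_lt(max(err3d[-c(10, 20)]), 1e-6)
  # report aggregation equals a brute-force pass
  expect_equal(rec$report$mean_re_side, mean(rec$points$re_side_px),
               tolerance = 1e-12)
  expect_equal(rec$report$stdev_re_top, sd(rec$points$re_top_px),
               tolerance = 1e-12)
  expect_lte(rec$report$n_flagged, rec$report$total_points)
  # empty overlap
  expect_error(reconstruct_trajectory(tw$rig, track_top, track_side, 500L),
               "empty")
  # offset alignment drops unpaired edge frames
  rec2 <- reconstruct_trajectory(tw$rig, track_top, track_side, 5L)
  expect_equal(rec2$report$total_points, n - 5)
})

test_that("3D error shrinks monotonically as pixel noise decreases", {
  set.seed(72)
  tw <- truth_rig()
  P <- c(4, -2, 50)
  pt <- project_points(tw$cams$top, P); ps <- project_points(tw$cams$side, P)
  med <- vapply(c(2, 1, 0.5, 0), function(s) {
    e <- replicate(500, {
      Q <- triangulate(tw$rig, pt + rnorm(2, 0, s), ps + rnorm(2, 0, s))
      sqrt(sum((Q - P)^2))
    })
    median(e)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  # at 1 px noise, median 3D error in the booth stays below 1 cm
  expect_lt(med[2], 1)
})

test_that("miscalibrated coverage degrades localization near the side camera", {
  # true cameras carry barrel distortion; calibration boards only cover the
  # central image region, so the distortion model extrapolates badly where
  # points near the lateral camera project (image periphery)
  set.seed(7)
  cfg <- scene_config()
  dist_true <- distortion(k1 = -0.12)
  cams <- true_cameras(cfg, dist_true, dist_true)
  spec <- board_spec(9, 6, 8.5)
  objp <- board_object_points(spec)
  central_poses <- function(n) lapply(1:n, function(i) {
    tl <- runif(2, -12, 12) * pi / 180
    R <- rodrigues_to_matrix(c(tl, runif(1, -0.4, 0.4)))
    ctr <- c(4, 2.5, 0) * 8.5
    pose(R, as.numeric(c(runif(2, -8, 8), 150 + runif(1, -15, 15)) - R %*% ctr))
  })
  obs_top <- make_board_obs(cams$top, central_poses(10), objp, noise = 0.3)
  obs_side <- make_board_obs(cams$side, central_poses(10), objp, noise = 0.3)
  sv <- render_calibration_set(cfg, board_spec(9, 6, 6), 8, "stereo",
                               noise_px = 0.3, render_images = FALSE,
                               distortion_top = dist_true,
                               distortion_side = dist_true)
  obs_st <- lapply(sv, function(v) list(top = v$top$observation,
                                        side = v$side$observation))
  cal <- run_calibrate(obs_top, obs_side, obs_st, c(cfg$width, cfg$height))
  pb <- sv[[1]]$top$pose; pw <- cams$top$pose
  R_wb <- t(pb$R) %*% pw$R
  t_wb <- as.numeric(t(pb$R) %*% (pw$t - pb$t))
  bias <- function(P) {
    est <- triangulate(cal$rig, project_points(cams$top, P),
                       project_points(cams$side, P))
    sqrt(sum((est - as.numeric(R_wb %*% P + t_wb))^2))
  }
  near_side_cam <- bias(c(36, 18, 64))
  at_center <- bias(c(0, 10, 50))
  expect_gt(near_side_cam, 2 * at_center)
})

test_that("study summaries reproduce the published roll-ups", {
  tb <- example_study_tables()
  s <- summarize_tables(tb$reprojection, tb$detections, image_width = 1280)
  expect_equal(round(s$overall_mean_re_px, 1), 3.7)
  expect_lt(s$high_error_pct, 5.4)
  expect_lt(s$mean_re_pct_of_width, 0.3)
  expect_equal(round(s$manual_pct, 1), 8.2)
  # single report: pass-through of its mean
  one <- tb$reprojection[1, ]
  expect_equal(summarize_tables(one)$overall_mean_re_px, one$mean_re)
})

test_that("trajectory CSV export has the documented columns", {
  tw <- truth_rig()
  pts <- make_trajectory(tw$cfg, 5)
  pt <- project_points(tw$cams$top, pts); ps <- project_points(tw$cams$side, pts)
  tr <- function(m) data.frame(frame_id = 1:5, u = m[, 1], v = m[, 2],
                               label = "automatic")
  rec <- reconstruct_trajectory(tw$rig, tr(pt), tr(ps), 0L)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(rec$points, f)
  back <- read.csv(f)
  expect_equal(names(back),
               c("frame_id", "X_cm", "Y_cm", "Z_cm", "u_top", "v_top",
                 "u_side", "v_side", "label_top", "label_side",
                 "re_top_px", "re_side_px", "flagged"))
})
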