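cfg_cal <- scene_config()
spec_cal <- board_spec(9, 6, 8.5)
objp_cal <- board_object_points(spec_cal)

test_that("single-camera calibration recovers a known camera", {
  set.seed(31)
  truth <- true_cameras(cfg_cal, distortion(k1 = -0.08, p1 = 5e-4))
  poses <- stereonut:::single_camera_board_poses(truth$top$intrinsics,
                                                 spec_cal, 10)
  obs <- make_board_obs(truth$top, poses, objp_cal, noise = 0)
  cal <- calibrate_camera(obs, c(cfg_cal$width, cfg_cal$height))
  ti <- truth$top$intrinsics
  expect_lt(abs(cal$intrinsics$fx - ti$fx) / ti$fx, 0.005)
  expect_lt(abs(cal$intrinsics$fy - ti$fy) / ti$fy, 0.005)
  expect_lt(cal$report$mean_re, 0.01)
  expect_lt(abs(cal$distortion$k1 - (-0.08)), 0.005)

  # with 0.3 px corner noise: mean RE on the order of the noise, fx within 2%
  obs_n <- make_board_obs(truth$top, poses, objp_cal, noise = 0.3)
  cal_n <- calibrate_camera(obs_n, c(cfg_cal$width, cfg_cal$height))
  expect_lt(abs(cal_n$intrinsics$fx - ti$fx) / ti$fx, 0.02)
  expect_gt(cal_n$report$mean_re, 0.05)
  expect_lt(cal_n$report$mean_re, 1)
})

test_that("calibration refuses under-constrained input", {
  truth <- true_cameras(cfg_cal)
  poses <- stereonut:::single_camera_board_poses(truth$top$intrinsics,
                                                 spec_cal, 3)
  obs <- make_board_obs(truth$top, poses[1:2], objp_cal)
  expect_error(calibrate_camera(obs, c(cfg_cal$width, cfg_cal$height)),
               "under-constrained")
})

test_that("calibration report matches a brute-force reprojection loop", {
  set.seed(32)
  truth <- true_cameras(cfg_cal)
  poses <- stereonut:::single_camera_board_poses(truth$top$intrinsics,
                                                 spec_cal, 5)
  obs <- make_board_obs(truth$top, poses, objp_cal, noise = 0.4)
  cal <- calibrate_camera(obs, c(cfg_cal$width, cfg_cal$height))
  errs <- unlist(lapply(seq_along(obs), function(i) {
    cam <- camera_model(cal$intrinsics, cal$distortion, cal$poses[[i]])
    pred <- project_points(cam, obs[[i]]$object_points)
    sqrt(rowSums((pred - obs[[i]]$image_points)^2))
  }))
  expect_equal(cal$report$mean_re, mean(errs), tolerance = 1e-12)
  expect_equal(cal$report$stdev_re, sd(errs), tolerance = 1e-12)
  expect_equal(cal$report$n_points, length(errs))
})

test_that("relative_pose satisfies the stereo composition identity", {
  p <- pose(random_rotation(), rnorm(3))
  r0 <- relative_pose(p, p)
  expect_equal(r0$R_rel, diag(3), tolerance = 1e-12)
  expect_equal(r0$t_rel, c(0, 0, 0), tolerance = 1e-12)
  p2 <- pose(random_rotation(), rnorm(3))
  r1 <- relative_pose(pose(), p2)
  expect_equal(r1$R_rel, p2$R); expect_equal(r1$t_rel, p2$t)
  set.seed(33)
  for (i in 1:10) {
    pa <- pose(random_rotation(), rnorm(3))
    pb <- pose(random_rotation(), rnorm(3))
    r <- relative_pose(pa, pb)
    expect_equal(r$R_rel %*% pa$R, pb$R, tolerance = 1e-12)
    expect_equal(as.numeric(r$R_rel %*% pa$t + r$t_rel), pb$t,
                 tolerance = 1e-12)
  }
})

test_that("essential matrix has the cross-product structure and rank 2", {
  E <- essential_matrix(diag(3), c(0, 0, 1))
  expect_equal(E, rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_error(essential_matrix(diag(3), c(0, 0, 0)), "degenerate")
  set.seed(34)
  for (i in 1:10) {
    R <- random_rotation(); t <- rnorm(3)
    sv <- svd(essential_matrix(R, t))$d
    expect_lt(abs(sv[1] - sv[2]), 1e-9 * sv[1])
    expect_lt(sv[3], 1e-9 * sv[1])
  }
})

test_that("E and F annihilate generated correspondences", {
  cams <- true_cameras(cfg_cal)
  rel <- relative_pose(cams$top$pose, cams$side$pose)
  E <- essential_matrix(rel$R_rel, rel$t_rel)
  F <- fundamental_matrix(E, cams$top$intrinsics, cams$side$intrinsics)
  expect_equal(fundamental_matrix(matrix(0, 3, 3), cams$top$intrinsics,
                                  cams$side$intrinsics), matrix(0, 3, 3))
  pts <- make_trajectory(cfg_cal, 40)
  pt <- project_points(cams$top, pts); ps <- project_points(cams$side, pts)
  for (i in seq_len(nrow(pts))) {
    pc_t <- world_to_camera(cams$top$pose, pts[i, ])
    pc_s <- world_to_camera(cams$side$pose, pts[i, ])
    x1 <- c(pc_t[1] / pc_t[3], pc_t[2] / pc_t[3], 1)
    x2 <- c(pc_s[1] / pc_s[3], pc_s[2] / pc_s[3], 1)
    expect_lt(abs(sum(x2 * (E %*% x1))), 1e-9)
    expect_lt(abs(sum(c(ps[i, ], 1) * (F %*% c(pt[i, ], 1)))), 1e-6)
  }
  set.seed(35)
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3)
    Fr <- fundamental_matrix(essential_matrix(R, t), cams$top$intrinsics,
                             cams$side$intrinsics)
    expect_lt(abs(det(Fr)), 1e-6 * norm(Fr, "F"))
  }
})

test_that("stereo calibration fuses board pairs into the true rig", {
  set.seed(36)
  truth <- true_cameras(cfg_cal)
  sspec <- board_spec(9, 6, 6.0)
  sv <- render_calibration_set(cfg_cal, sspec, 8, "stereo",
                               render_images = FALSE)
  obs <- lapply(sv, function(v) list(top = v$top$observation,
                                     side = v$side$observation))
  cam_top <- camera_model(truth$top$intrinsics, truth$top$distortion)
  cam_side <- camera_model(truth$side$intrinsics, truth$side$distortion)
  st <- calibrate_stereo(obs, cam_top, cam_side)
  rel_true <- relative_pose(truth$top$pose, truth$side$pose)
  expect_lt(stereonut:::rotation_angle_deg(st$rig$R_rel %*% t(rel_true$R_rel)),
            0.05)
  # the two optical axes of the layout are 90 degrees apart
  axis_angle <- acos(sum(st$rig$R_rel[3, ] * c(0, 0, 1))) * 180 / pi
  expect_lt(abs(axis_angle - 90), 0.05)
  expect_lt(st$report$mean_re_stereo, 0.01)
  expect_lt(max(abs(st$rig$t_rel - rel_true$t_rel)), 0.05)

  # a single pair: the rig is exactly that pair's relative pose
  st1 <- calibrate_stereo(obs[1], cam_top, cam_side)
  p1 <- solve_pnp(obs[[1]]$top, cam_top$intrinsics, cam_top$distortion)
  p2 <- solve_pnp(obs[[1]]$side, cam_side$intrinsics, cam_side$distortion)
  rel1 <- relative_pose(p1, p2)
  expect_equal(st1$rig$R_rel, rel1$R_rel, tolerance = 1e-9)
  expect_equal(st1$rig$t_rel, rel1$t_rel, tolerance = 1e-7)
})

test_that("stereo calibration under noise stays sub-pixel; inconsistency errors", {
  set.seed(37)
  truth <- true_cameras(cfg_cal)
  sspec <- board_spec(9, 6, 6.0)
  sv <- render_calibration_set(cfg_cal, sspec, 8, "stereo", noise_px = 0.3,
                               render_images = FALSE)
  obs <- lapply(sv, function(v) list(top = v$top$observation,
                                     side = v$side$observation))
  cam_top <- camera_model(truth$top$intrinsics, truth$top$distortion)
  cam_side <- camera_model(truth$side$intrinsics, truth$side$distortion)
  st <- calibrate_stereo(obs, cam_top, cam_side)
  expect_lt(st$report$mean_re_stereo, 1)

  # one pair observed through a side camera rotated by 10 degrees -> spread
  bad_side <- camera_model(truth$side$intrinsics, truth$side$distortion,
                           pose(rodrigues_to_matrix(c(0, 0.175, 0)) %*%
                                  truth$side$pose$R, truth$side$pose$t))
  obs_bad <- obs
  p_bad <- sv[[2]]$top$pose  # board pose in top camera frame
  rel_ts <- relative_pose(truth$top$pose, bad_side$pose)
  pose_bad_side <- pose(rel_ts$R_rel %*% p_bad$R,
                        as.numeric(rel_ts$R_rel %*% p_bad$t + rel_ts$t_rel))
  obs_bad[[2]]$side <- make_board_obs(
    camera_model(truth$side$intrinsics, truth$side$distortion),
    list(pose_bad_side), board_object_points(sspec))[[1]]
  expect_error(calibrate_stereo(obs_bad, cam_top, cam_side), "unstable")
})

test_that("rig YAML round-trips", {
  cams <- true_cameras(cfg_cal)
  rel <- relative_pose(cams$top$pose, cams$side$pose)
  rig <- stereo_rig(cams$top, cams$side, rel$R_rel, rel$t_rel)
  f <- tempfile(fileext = ".yaml")
  write_rig_yaml(rig, f)
  rig2 <- read_rig_yaml(f)
  expect_identical(rig2$R_rel, rig$R_rel)
  expect_identical(rig2$t_rel, rig$t_rel)
  expect_equal(rig2$F, rig$F, tolerance = 1e-15)
})
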