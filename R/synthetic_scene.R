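# Ground-truthed synthetic stereo scenes.
#
# Emulates the recording booth: a cylindrical cabin (100 cm tall, 93 cm
# radius) with a zenithal camera at 130 cm looking down and a lateral camera
# at 55 cm on the wall looking at the plant axis, 90 degrees apart; 1280x720
# frames with 112-degree-FOV optics; a 16:8-patterned light/dark photoperiod
# (scaled to frames); a dark lower band in the side view; an optional
# support pole. The plant is a stem polyline from the pot to a helically
# nutating tip with a darker tip blob: enough structure to exercise
# segmentation, geodesic tip finding, epipolar selection and triangulation,
# with exact ground truth for every stage.

#' Synthetic scene configuration
#'
#' Lengths in cm, intensities on a 0-255 scale. The photoperiod is scaled
#' from hours to frames (default 40 light : 20 dark) so test sequences run
#' in minutes; one real day at one frame per minute would be 960:480.
#'
#' @param width,height Frame size in pixels.
#' @param fov_deg Horizontal field of view of both cameras (degrees).
#' @param booth_radius,booth_height Booth cylinder (cm).
#' @param side_cam_height,top_cam_height Camera heights (cm).
#' @param light_frames,dark_frames Photoperiod pattern lengths (frames).
#' @param light_level,dark_level Illumination multipliers of the two phases
#'   (the dark phase emulates the dim safelight).
#' @param photo_phase Frame offset of the photoperiod pattern.
#' @param pole `NULL`, or `list(height, diameter, distance)` in cm for the
#'   support-pole condition.
#' @param pixel_noise Additive Gaussian pixel-noise s.d. (intensity levels).
#' @param stem_base_z Height of the pot rim where the stem starts (cm).
#' @param seed RNG seed; a fixed seed makes rendering bit-identical.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 1280L, height = 720L, fov_deg = 112,
                         booth_radius = 93, booth_height = 100,
                         side_cam_height = 55, top_cam_height = 130,
                         light_frames = 40L, dark_frames = 20L,
                         light_level = 1.0, dark_level = 0.2,
                         photo_phase = 0L,
                         pole = NULL, pixel_noise = 2, stem_base_z = 10,
                         seed = 1L) {
  stopifnot(width > 0, height > 0, fov_deg > 0, fov_deg < 180,
            booth_radius > 0, booth_height > 0,
            light_frames > 0, dark_frames > 0)
  if (!is.null(pole))
    stopifnot(pole$height > 0, pole$diameter > 0, pole$distance > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fov_deg = fov_deg, booth_radius = booth_radius,
                 booth_height = booth_height,
                 side_cam_height = side_cam_height,
                 top_cam_height = top_cam_height,
                 light_frames = as.integer(light_frames),
                 dark_frames = as.integer(dark_frames),
                 light_level = light_level, dark_level = dark_level,
                 photo_phase = as.integer(photo_phase),
                 pole = pole, pixel_noise = pixel_noise,
                 stem_base_z = stem_base_z, seed = as.integer(seed),
                 intensity = list(bg = 200, dark_band = 90, pot = 120,
                                  stem = 60, tip = 20, pole = 50)),
            class = "scene_config")
}

#' Ground-truth cameras of the synthetic rig
#'
#' World frame: origin at the pot center on the booth floor, z up. The top
#' camera looks straight down from the booth axis; the side camera sits on
#' the booth wall (+x) looking at the axis. Focal length follows from the
#' field of view: fx = (width/2) / tan(fov/2).
#'
#' @param cfg A [scene_config()].
#' @param distortion_top,distortion_side Optional [distortion()] objects.
#' @return List with `top` and `side` [camera_model()]s.
#' @export
true_cameras <- function(cfg, distortion_top = distortion(),
                         distortion_side = distortion()) {
  f <- (cfg$width / 2) / tan(cfg$fov_deg / 2 * pi / 180)
  intr <- intrinsics(f, f, (cfg$width - 1) / 2, (cfg$height - 1) / 2,
                     cfg$width, cfg$height)
  # top: camera axes in world rows of R; z_cam = -z_w, x_cam = +x_w
  R_top <- rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  C_top <- c(0, 0, cfg$top_cam_height)
  # side: at (+booth_radius, 0, h) looking along -x; u axis = +y_w, v = -z_w
  R_side <- rbind(c(0, 1, 0), c(0, 0, -1), c(-1, 0, 0))
  C_side <- c(cfg$booth_radius, 0, cfg$side_cam_height)
  list(top = camera_model(intr, distortion_top,
                          pose(R_top, as.numeric(-R_top %*% C_top))),
       side = camera_model(intr, distortion_side,
                           pose(R_side, as.numeric(-R_side %*% C_side))))
}

#' Helical nutation trajectory of the tip
#'
#' Circular (x, y) motion of given radius about the plant axis with steady
#' vertical growth: the standard idealization of circumnutation.
#'
#' @param cfg A [scene_config()].
#' @param n_frames Number of frames.
#' @param radius Nutation radius (cm).
#' @param period Nutation period (frames); must be positive.
#' @param growth_rate Vertical growth (cm/frame).
#' @param z0 Tip height at the first frame (cm).
#' @param phase0 Starting phase (radians).
#' @param t0 Time index of the first frame (frames; supports extended
#'   timelines for offset sequences).
#' @return n x 3 matrix of tip positions (cm).
#' @export
make_trajectory <- function(cfg, n_frames, radius = 6, period = 200,
                            growth_rate = 0.03, z0 = 35, phase0 = 0, t0 = 0) {
  stopifnot(period > 0, n_frames >= 1)
  t <- t0 + seq_len(n_frames) - 1
  th <- phase0 + 2 * pi * t / period
  xyz <- cbind(radius * cos(th), radius * sin(th), z0 + growth_rate * t)
  if (max(sqrt(xyz[, 1]^2 + xyz[, 2]^2)) > cfg$booth_radius ||
      max(xyz[, 3]) > cfg$booth_height)
    warning("trajectory leaves the booth cylinder")
  xyz
}

#' Photoperiod illumination schedule
#' @param cfg A [scene_config()].
#' @param t Time indices (frames, 0-based).
#' @return Numeric multipliers (light_level or dark_level).
#' @export
illumination_at <- function(cfg, t) {
  cyc <- (t + cfg$photo_phase) %% (cfg$light_frames + cfg$dark_frames)
  ifelse(cyc < cfg$light_frames, cfg$light_level, cfg$dark_level)
}

# stem polyline in 3D: gentle quadratic bend from the pot to the tip
stem_polyline <- function(cfg, tip, n = 30) {
  b <- c(0, 0, cfg$stem_base_z)
  ctrl <- c(0.25 * tip[1], 0.25 * tip[2],
            cfg$stem_base_z + 0.65 * (tip[3] - cfg$stem_base_z))
  s <- seq(0, 1, length.out = n)
  cbind((1 - s)^2 * b[1] + 2 * s * (1 - s) * ctrl[1] + s^2 * tip[1],
        (1 - s)^2 * b[2] + 2 * s * (1 - s) * ctrl[2] + s^2 * tip[2],
        (1 - s)^2 * b[3] + 2 * s * (1 - s) * ctrl[3] + s^2 * tip[3])
}

# anti-aliased thick polyline; pts = n x 2 pixel coords, width in px
draw_polyline <- function(img, pts, width_px, intensity) {
  nr <- nrow(img); nc <- ncol(img)
  hw <- width_px / 2
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    lo_u <- floor(min(a[1], b[1]) - hw - 1); hi_u <- ceiling(max(a[1], b[1]) + hw + 1)
    lo_v <- floor(min(a[2], b[2]) - hw - 1); hi_v <- ceiling(max(a[2], b[2]) + hw + 1)
    cs <- max(1L, lo_u + 1L):min(nc, hi_u + 1L)
    rs <- max(1L, lo_v + 1L):min(nr, hi_v + 1L)
    if (!length(cs) || !length(rs) || cs[1] > cs[length(cs)] || rs[1] > rs[length(rs)]) next
    u <- matrix(cs - 1, length(rs), length(cs), byrow = TRUE)
    v <- matrix(rs - 1, length(rs), length(cs))
    ab <- b - a; L2 <- sum(ab^2)
    tpar <- if (L2 > 0) pmin(pmax(((u - a[1]) * ab[1] + (v - a[2]) * ab[2]) / L2, 0), 1) else 0
    d <- sqrt((u - (a[1] + tpar * ab[1]))^2 + (v - (a[2] + tpar * ab[2]))^2)
    cov <- pmin(pmax(hw + 0.5 - d, 0), 1)
    img[rs, cs] <- img[rs, cs] * (1 - cov) + intensity * cov
  }
  img
}

draw_disk <- function(img, center, radius_px, intensity) {
  nr <- nrow(img); nc <- ncol(img)
  cs <- max(1L, floor(center[1] - radius_px)):min(nc, ceiling(center[1] + radius_px + 2))
  rs <- max(1L, floor(center[2] - radius_px)):min(nr, ceiling(center[2] + radius_px + 2))
  if (!length(cs) || !length(rs)) return(img)
  u <- matrix(cs - 1, length(rs), length(cs), byrow = TRUE)
  v <- matrix(rs - 1, length(rs), length(cs))
  d <- sqrt((u - center[1])^2 + (v - center[2])^2)
  cov <- pmin(pmax(radius_px + 0.5 - d, 0), 1)
  img[rs, cs] <- img[rs, cs] * (1 - cov) + intensity * cov
  img
}

#' Render one synthetic stereo frame pair
#'
#' Bright booth background with a dark lower band in the side view and a
#' dark pot disk in the top view; the stem polyline and a darker circular
#' tip blob; the optional pole; a global illumination multiplier and
#' additive Gaussian pixel noise (drawn from the current RNG state).
#'
#' @param cfg A [scene_config()].
#' @param cams Cameras from [true_cameras()].
#' @param tip Length-3 tip position (cm); must project into at least one view.
#' @param illumination Global multiplier (1 = lights on).
#' @param noise Logical; add pixel noise.
#' @return List with `top` and `side` intensity matrices (0-255).
#' @export
render_frame <- function(cfg, cams, tip, illumination = 1, noise = TRUE) {
  ins <- cfg$intensity
  stem <- stem_polyline(cfg, tip)
  inside <- function(cam) {
    p <- tryCatch(project_points(cam, tip), error = function(e) NULL)
    !is.null(p) && all(p[, 1] >= 0 & p[, 1] <= cfg$width - 1 &
                         p[, 2] >= 0 & p[, 2] <= cfg$height - 1)
  }
  if (!inside(cams$top) && !inside(cams$side))
    stop("tip out of frame in both views")

  render_one <- function(cam, view) {
    img <- matrix(ins$bg, cfg$height, cfg$width)
    if (view == "side") {
      # dark band: everything below the projected horizon of z = 18 cm
      horizon <- project_points(cam, c(0, 0, 18))[2]
      rows <- seq_len(cfg$height) - 1
      img[rows > horizon, ] <- ins$dark_band
    } else {
      pot_c <- project_points(cam, c(0, 0, 0))
      pot_r <- cam$intrinsics$fx * 9 / (cfg$top_cam_height)
      img <- draw_disk(img, pot_c, pot_r, ins$pot)
    }
    if (!is.null(cfg$pole)) {
      pz <- seq(0, cfg$pole$height, length.out = 20)
      ppts <- project_points(cam, cbind(0, -cfg$pole$distance, pz))
      depth <- world_to_camera(cam$pose, cbind(0, -cfg$pole$distance, pz))[, 3]
      wpx <- mean(cam$intrinsics$fx * cfg$pole$diameter / depth)
      img <- draw_polyline(img, ppts, max(wpx, 1.5), ins$pole)
    }
    spts <- project_points(cam, stem)
    sdepth <- world_to_camera(cam$pose, stem)[, 3]
    swidth <- pmax(cam$intrinsics$fx * 0.35 / mean(sdepth), 1.8)
    img <- draw_polyline(img, spts, swidth, ins$stem)
    tp <- project_points(cam, tip)
    tdepth <- world_to_camera(cam$pose, tip)[, 3]
    trad <- max(cam$intrinsics$fx * 0.45 / tdepth, 2.2)
    img <- draw_disk(img, tp, trad, ins$tip)
    img <- img * illumination
    if (noise && cfg$pixel_noise > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, cfg$pixel_noise),
                          nrow(img), ncol(img))
    pmin(pmax(img, 0), 255)
  }
  list(top = render_one(cams$top, "top"), side = render_one(cams$side, "side"))
}

#' Generate a synchronized (offset) stereo sequence with ground truth
#'
#' The side sequence is shifted by `offset_frames` (an event at top frame f
#' appears at side frame f + offset). Photoperiod lighting steps are
#' injected in both sequences; the ground-truth manifest records per-frame
#' tip positions, true projections and illumination, plus the injected
#' offset and true lighting-change frames.
#'
#' @param cfg A [scene_config()].
#' @param n_frames Frames per view.
#' @param offset_frames Signed side-vs-top offset; |offset| < n_frames.
#' @param dir Output directory: frames are written as PNG under `top/` and
#'   `side/` with the manifest and camera truth alongside. When `NULL`,
#'   frames are returned in memory (keep n_frames modest).
#' @param trajectory Optional precomputed trajectory parameters, a list
#'   passed to [make_trajectory()].
#' @return List with `truth` (manifest data frame), `cams`, `offset_frames`,
#'   `lighting_changes_top`, `lighting_changes_side`, and either `dir` or
#'   `frames_top`/`frames_side`.
#' @export
generate_sequence_pair <- function(cfg, n_frames, offset_frames = 0L,
                                   dir = NULL, trajectory = list()) {
  stopifnot(abs(offset_frames) < n_frames)
  set.seed(cfg$seed)
  cams <- true_cameras(cfg)
  # truth over the extended timeline covering both cameras
  t_lo <- min(0, -offset_frames); t_hi <- max(n_frames - 1, n_frames - 1 - offset_frames)
  traj <- do.call(make_trajectory,
                  c(list(cfg = cfg, n_frames = t_hi - t_lo + 1, t0 = t_lo),
                    trajectory))
  traj_at <- function(t) traj[t - t_lo + 1, , drop = FALSE]
  illum_seq <- illumination_at(cfg, t_lo:t_hi)
  illum_at <- function(t) illum_seq[t - t_lo + 1]
  # 1-based frame indices whose illumination differs from the previous frame
  changes <- function(ts) which(diff(illum_at(ts)) != 0) + 1L

  top_t <- 0:(n_frames - 1)
  side_t <- top_t - offset_frames  # truth time shown in side frame i
  write_frames <- !is.null(dir)
  if (write_frames) {
    dir.create(file.path(dir, "top"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "side"), recursive = TRUE, showWarnings = FALSE)
  }
  frames_top <- if (!write_frames) vector("list", n_frames)
  frames_side <- if (!write_frames) vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    ft <- render_frame(cfg, cams, as.numeric(traj_at(top_t[i])),
                       illum_at(top_t[i]))$top
    fs <- render_frame(cfg, cams, as.numeric(traj_at(side_t[i])),
                       illum_at(side_t[i]))$side
    if (write_frames) {
      png::writePNG(ft / 255, file.path(dir, "top", sprintf("frame_%05d.png", i)))
      png::writePNG(fs / 255, file.path(dir, "side", sprintf("frame_%05d.png", i)))
    } else {
      frames_top[[i]] <- ft; frames_side[[i]] <- fs
    }
  }
  proj_top <- project_points(cams$top, traj_at(top_t))
  proj_side <- project_points(cams$side, traj_at(top_t))
  truth <- data.frame(frame_id = seq_len(n_frames),
                      X = traj_at(top_t)[, 1], Y = traj_at(top_t)[, 2],
                      Z = traj_at(top_t)[, 3],
                      u_top = proj_top[, 1], v_top = proj_top[, 2],
                      u_side = proj_side[, 1], v_side = proj_side[, 2],
                      illumination = illum_at(top_t))
  out <- list(truth = truth, cams = cams, offset_frames = as.integer(offset_frames),
              lighting_changes_top = changes(top_t),
              lighting_changes_side = changes(side_t))
  if (write_frames) {
    utils::write.csv(truth, file.path(dir, "truth_manifest.csv"), row.names = FALSE)
    write_camera_yaml(cams$top, file.path(dir, "camera_top.yaml"))
    write_camera_yaml(cams$side, file.path(dir, "camera_side.yaml"))
    out$dir <- dir
  } else {
    out$frames_top <- frames_top; out$frames_side <- frames_side
  }
  out
}

# ---- calibration-set rendering ----------------------------------------------

# board pose in a camera frame -> camera_model whose "world" is the board frame
board_view_camera <- function(intr, dist, pose_bc) camera_model(intr, dist, pose_bc)

#' Render a chessboard as seen by a camera
#'
#' Inverse-maps pixels through the lens model onto the board plane
#' (exact, including distortion) with supersampled anti-aliasing. The board
#' has a white margin of 0.7 squares; the square diagonally up-left of the
#' origin inner corner is black.
#'
#' @param intr,dist Camera [intrinsics()] and [distortion()].
#' @param pose_bc Board-to-camera [pose()].
#' @param spec A [board_spec()].
#' @param supersample Subpixel samples per axis.
#' @param noise_sd Additive intensity noise (0-255 scale).
#' @return List with `image` (matrix 0-255) and `corners` (true inner-corner
#'   pixels, row-major, N x 2).
#' @export
render_board_image <- function(intr, dist, pose_bc, spec, supersample = 3L,
                               noise_sd = 0) {
  cam <- camera_model(intr, dist, pose_bc)
  s <- spec$square_size
  margin <- 0.7 * s
  xr <- c(-s - margin, spec$inner_cols * s + margin)
  yr <- c(-s - margin, spec$inner_rows * s + margin)
  boundary <- rbind(
    cbind(seq(xr[1], xr[2], length.out = 25), yr[1], 0),
    cbind(xr[2], seq(yr[1], yr[2], length.out = 25), 0),
    cbind(seq(xr[2], xr[1], length.out = 25), yr[2], 0),
    cbind(xr[1], seq(yr[2], yr[1], length.out = 25), 0))
  bp <- project_points(cam, boundary)
  cs <- max(1L, floor(min(bp[, 1]))):min(intr$width, ceiling(max(bp[, 1])) + 1L)
  rs <- max(1L, floor(min(bp[, 2]))):min(intr$height, ceiling(max(bp[, 2])) + 1L)
  img <- matrix(128, intr$height, intr$width)
  if (length(cs) && length(rs)) {
    R <- pose_bc$R; t <- pose_bc$t
    a <- R[, 1]; b <- R[, 2]
    axb <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
    mtxb <- c(-t[2] * b[3] + t[3] * b[2], -t[3] * b[1] + t[1] * b[3],
              -t[1] * b[2] + t[2] * b[1])
    axmt <- c(-a[2] * t[3] + a[3] * t[2], -a[3] * t[1] + a[1] * t[3],
              -a[1] * t[2] + a[2] * t[1])
    ss <- supersample
    offs <- (seq_len(ss) - (ss + 1) / 2) / ss
    acc <- matrix(0, length(rs), length(cs))
    for (ou in offs) for (ov in offs) {
      u <- rep(cs - 1 + ou, each = length(rs))
      v <- rep(rs - 1 + ov, times = length(cs))
      xy <- remove_distortion(dist, cbind((u - intr$cx) / intr$fx,
                                          (v - intr$cy) / intr$fy))
      cdir <- cbind(-xy[, 1], -xy[, 2], -1)
      den <- axb[1] * cdir[, 1] + axb[2] * cdir[, 2] + axb[3] * cdir[, 3]
      X <- (mtxb[1] * cdir[, 1] + mtxb[2] * cdir[, 2] + mtxb[3] * cdir[, 3]) / den
      Y <- (axmt[1] * cdir[, 1] + axmt[2] * cdir[, 2] + axmt[3] * cdir[, 3]) / den
      depth <- -(axb[1] * t[1] + axb[2] * t[2] + axb[3] * t[3]) / den
      col <- rep(128, length(u))
      on_board <- depth > 0 & X >= xr[1] & X <= xr[2] & Y >= yr[1] & Y <= yr[2]
      col[on_board] <- 230
      in_sq <- on_board & X >= -s & X < spec$inner_cols * s &
        Y >= -s & Y < spec$inner_rows * s
      i <- floor(X[in_sq] / s); j <- floor(Y[in_sq] / s)
      col[in_sq] <- ifelse((i + j) %% 2 == 0, 30, 230)
      acc <- acc + matrix(col, length(rs), length(cs))
    }
    img[rs, cs] <- acc / (ss * ss)
  }
  if (noise_sd > 0)
    img <- pmin(pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                  nrow(img), ncol(img)), 0), 255)
  list(image = img, corners = project_points(cam, board_object_points(spec)))
}

# deterministic varied board poses in front of one camera
single_camera_board_poses <- function(intr, spec, n_views) {
  s <- spec$square_size
  bw <- (spec$inner_cols + 1) * s; bh <- (spec$inner_rows + 1) * s
  d0 <- max(bw, bh) * intr$fx / (0.62 * min(intr$width, intr$height)) # fills ~60%
  ctr <- c((spec$inner_cols - 1) / 2 * s, (spec$inner_rows - 1) / 2 * s, 0)
  # lateral amplitudes that sweep the board across the frame while keeping a
  # 50 px safety margin at the closest distance used
  dmin <- 0.85 * d0
  au <- 0.8 * max(dmin * (intr$width / 2 - 50) / intr$fx - bw / 2, 0)
  av <- 0.8 * max(dmin * (intr$height / 2 - 50) / intr$fx - bh / 2, 0)
  tilts <- rbind(c(0, 0), c(18, 0), c(-18, 0), c(0, 18), c(0, -18),
                 c(14, 14), c(-14, 14), c(14, -14), c(-14, -14), c(24, 8))
  lapply(seq_len(n_views), function(i) {
    tl <- tilts[(i - 1) %% nrow(tilts) + 1, ] * pi / 180
    roll <- 0.1 + (i - 1) * 0.25
    Rz <- rodrigues_to_matrix(c(0, 0, roll))
    Rt <- rodrigues_to_matrix(c(tl[1], tl[2], 0))
    # half-turn about x so the board's front (+z) face looks at the camera
    R <- Rt %*% Rz %*% diag(c(1, -1, -1))
    lateral <- c(au * cos(2.4 * i), av * sin(2.4 * i))
    d <- d0 * (1 + 0.15 * sin(1.7 * i))
    # shrink the lateral offset until the whole grid projects with margin
    # (tilted boards spill wider than the fronto-parallel estimate)
    objp <- board_object_points(spec)
    cam0 <- camera_model(intr)
    for (shrink in 0.85^(0:12)) {
      p <- pose(R, as.numeric(c(lateral * shrink, d) - R %*% ctr))
      uv <- project_points(camera_model(intr, pose = p), objp)
      if (all(uv[, 1] >= 12 & uv[, 1] <= intr$width - 13 &
              uv[, 2] >= 12 & uv[, 2] <= intr$height - 13)) return(p)
    }
    pose(R, as.numeric(c(0, 0, d * 1.2) - R %*% ctr))
  })
}

#' Render a calibration image set with ground truth
#'
#' Places the board at varied poses in front of the requested camera (or,
#' for `which = "stereo"`, at poses visible in both cameras of the rig) and
#' returns rendered images, true corner projections and true poses.
#'
#' @param cfg A [scene_config()].
#' @param spec A [board_spec()].
#' @param n_views Number of views (>= 3 for single-camera, >= 1 for stereo).
#' @param which `"top"`, `"side"` or `"stereo"`.
#' @param noise_px Gaussian noise added to the returned corner observations
#'   (px); images themselves stay noiseless unless `noise_sd` is set.
#' @param render_images Render rasters (`TRUE`) or return only geometric
#'   truth (fast path for calibration tests).
#' @param noise_sd Pixel-intensity noise of rendered images.
#' @param distortion_top,distortion_side True lens distortion.
#' @return For single cameras: list of views, each with `observation` (a
#'   `board_observation` built from true corners plus `noise_px` noise),
#'   `true_corners`, `pose` and optionally `image`. For stereo: per view a
#'   list with `top` and `side` sub-views of that structure.
#' @export
render_calibration_set <- function(cfg, spec, n_views,
                                   which = c("top", "side", "stereo"),
                                   noise_px = 0, render_images = TRUE,
                                   noise_sd = 0,
                                   distortion_top = distortion(),
                                   distortion_side = distortion()) {
  which <- match.arg(which)
  if (which == "stereo") stopifnot(n_views >= 1) else stopifnot(n_views >= 3)
  cams <- true_cameras(cfg, distortion_top, distortion_side)
  objp <- board_object_points(spec)
  make_view <- function(intr, dist, pose_bc, fid) {
    cam <- camera_model(intr, dist, pose_bc)
    corners <- project_points(cam, objp)
    if (any(corners[, 1] < 2 | corners[, 1] > intr$width - 3 |
            corners[, 2] < 2 | corners[, 2] > intr$height - 3))
      stop("invisible board: corners project outside the image")
    obs_pts <- corners
    if (noise_px > 0)
      obs_pts <- obs_pts + matrix(stats::rnorm(length(obs_pts), 0, noise_px),
                                  nrow(obs_pts), 2)
    v <- list(observation = structure(list(image_points = obs_pts,
                                           object_points = objp,
                                           frame_id = fid),
                                      class = "board_observation"),
              true_corners = corners, pose = pose_bc)
    if (render_images)
      v$image <- render_board_image(intr, dist, pose_bc, spec,
                                    noise_sd = noise_sd)$image
    v
  }
  if (which != "stereo") {
    cam <- cams[[which]]
    poses <- single_camera_board_poses(cam$intrinsics, spec, n_views)
    return(lapply(seq_len(n_views), function(i)
      make_view(cam$intrinsics, cam$distortion, poses[[i]], i)))
  }
  # stereo: board tilted between the two optical axes near the plant volume
  lapply(seq_len(n_views), function(i) {
    ang <- (-40 + 80 * ((i - 1) %% 5) / 4) * pi / 180 / 4  # mild sweep
    tilt <- pi / 4 + ang  # ~45 deg between up and +x
    ey <- c(0, 1, 0)
    n <- c(sin(tilt), 0, cos(tilt))
    ex <- c(n[3], 0, -n[1])  # in-plane, toward +x/-z
    Rb <- cbind(ex, ey, n)   # board frame -> world
    roll <- 0.15 * sin(2.1 * i)
    Rb <- Rb %*% rodrigues_to_matrix(c(0, 0, roll))
    centre <- c(15 + 3 * sin(1.3 * i), 5 * cos(1.1 * i), 50 + 4 * sin(0.9 * i))
    ctr <- c((spec$inner_cols - 1) / 2 * spec$square_size,
             (spec$inner_rows - 1) / 2 * spec$square_size, 0)
    c0 <- centre - as.numeric(Rb %*% ctr)
    view_for <- function(cam) {
      pose_bc <- pose(cam$pose$R %*% Rb,
                      as.numeric(cam$pose$R %*% c0 + cam$pose$t))
      make_view(cam$intrinsics, cam$distortion, pose_bc, NA)
    }
    list(top = view_for(cams$top), side = view_for(cams$side))
  })
}
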