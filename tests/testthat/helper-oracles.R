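# independent reference implementations used as oracles

# brute-force Dijkstra over the 8-connected foreground of a mask (O(V^2));
# src_uv 0-based; returns matrix of distances indexed like mask
brute_dijkstra <- function(mask, src_uv) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask != 0)
  vr <- ((idx - 1) %% nr) + 1
  vc <- ((idx - 1) %/% nr) + 1
  n <- length(idx)
  d <- rep(Inf, n)
  src <- which(vc - 1 == src_uv[1] & vr - 1 == src_uv[2])
  stopifnot(length(src) == 1)
  d[src] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, d))
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    dr <- abs(vr - vr[u]); dc <- abs(vc - vc[u])
    nb <- which(!done & dr <= 1 & dc <= 1 & (dr + dc) > 0)
    w <- ifelse(dr[nb] + dc[nb] == 2, sqrt(2), 1)
    d[nb] <- pmin(d[nb], d[u] + w)
  }
  out <- matrix(Inf, nr, nc)
  out[idx] <- d
  out
}

# term-by-term evaluation of the distortion polynomial (independent of the
# vectorized implementation)
distort_ref <- function(d, x, y) {
  r2 <- x * x + y * y
  rad <- 1 + d$k1 * r2 + d$k2 * r2 * r2 + d$k3 * r2 * r2 * r2
  c(x * rad + (d$p2 * (r2 + 2 * x * x) + 2 * d$p1 * x * y),
    y * rad + (d$p1 * (r2 + 2 * y * y) + 2 * d$p2 * x * y))
}

# 4x4 homogeneous-matrix evaluation of the world-to-camera change of basis
world_to_camera_ref <- function(R, t, pw) {
  M <- rbind(cbind(R, t), c(0, 0, 0, 1))
  as.numeric((M %*% c(pw, 1))[1:3])
}

cand_df <- function(...) {
  m <- rbind(...)
  structure(data.frame(u = m[, 1], v = m[, 2], contour_id = seq_len(nrow(m)),
                       geodesic_score = 0),
            class = c("candidate_set", "data.frame"))
}

random_rotation <- function() {
  rodrigues_to_matrix(stats::rnorm(3))
}

# small standard scene + cached calibration observation sets shared by tests
scene_small <- function(...) scene_config(width = 640L, height = 360L, ...)

make_board_obs <- function(cam, poses, objp, noise = 0) {
  lapply(seq_along(poses), function(i) {
    cm <- camera_model(cam$intrinsics, cam$distortion, poses[[i]])
    pts <- project_points(cm, objp)
    if (noise > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, noise), nrow(pts), 2)
    structure(list(image_points = pts, object_points = objp, frame_id = i),
              class = "board_observation")
  })
}
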