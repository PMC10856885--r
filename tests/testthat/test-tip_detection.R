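test_that("min_path_tip matches a brute-force Dijkstra oracle", {
  set.seed(51)
  for (trial in 1:6) {
    # random connected blob on a small grid
    m <- matrix(0L, 40, 48)
    r <- 20 + round(cumsum(rnorm(60)))
    c <- 5 + round(cumsum(abs(rnorm(60)) * 0.8))
    r <- pmin(pmax(r, 2), 39); c <- pmin(pmax(c, 2), 47)
    for (k in seq_along(r)) m[(r[k] - 1):(r[k] + 1), (c[k] - 1):(c[k] + 1)] <- 1L
    ct <- extract_contours(m, min_area = 1)[[1]]
    base <- c(c[1] - 1, r[1] - 1)
    tip <- min_path_tip(ct$pixels, base)
    # oracle from the same source pixel
    src <- tip$source
    d_ref <- brute_dijkstra(m, src)
    expect_equal(tip$score, max(d_ref[is.finite(d_ref)]), tolerance = 1e-9)
    expect_equal(d_ref[tip$pixel[["v"]] + 1, tip$pixel[["u"]] + 1],
                 tip$score, tolerance = 1e-9)
  }
})

test_that("the geodesic endpoint of a hook differs from the Euclidean argmax", {
  m <- matrix(0L, 50, 70)
  m[2:3, 2:61] <- 1L     # run right along the top
  m[2:41, 60:61] <- 1L   # down
  m[40:41, 10:61] <- 1L  # back left
  m[20:41, 10:11] <- 1L  # up: endpoint near the start
  ct <- extract_contours(m, min_area = 1)[[1]]
  base <- c(1, 1)
  tip <- min_path_tip(ct$pixels, base)
  # Euclidean-farthest pixel is the lower-right elbow, not the hook end
  d_euc <- sqrt((ct$pixels[, 1] - base[1])^2 + (ct$pixels[, 2] - base[2])^2)
  euc_px <- ct$pixels[which.max(d_euc), ]
  expect_gt(sqrt(sum((tip$pixel - euc_px)^2)), 20)
  # the hook end is at (u ~ 9-10, v ~ 19-20)
  expect_lt(abs(tip$pixel[["u"]] - 10), 2.5)
  expect_lt(abs(tip$pixel[["v"]] - 20), 2.5)
  d_ref <- brute_dijkstra(m, tip$source)
  expect_equal(tip$score, max(d_ref[is.finite(d_ref)]), tolerance = 1e-9)
})

test_that("a straight bar yields its far end within path-length bounds", {
  m <- matrix(0L, 120, 20)
  m[11:110, 9:11] <- 1L  # vertical bar, length 100 px, 3 px wide
  ct <- extract_contours(m, min_area = 1)[[1]]
  tip <- min_path_tip(ct$pixels, c(9, 10))
  expect_equal(tip$pixel[["v"]], 109)
  expect_gte(tip$score, 98)
  expect_lte(tip$score, 100 * sqrt(2))
  # single-pixel fragment
  one <- matrix(c(5, 7), 1, 2)
  t1 <- min_path_tip(one, c(5, 7))
  expect_equal(unname(t1$pixel), c(5, 7))
  expect_equal(t1$score, 0)
})

test_that("top-view candidates come one per contour, ranked by area", {
  expect_equal(nrow(extract_candidates_top(list(), base_anchor("top", 0, 0))), 0)
  m <- matrix(0L, 60, 60)
  m[10:40, 10:12] <- 1L   # large bar
  m[50:55, 40:45] <- 1L   # small blob
  cts <- extract_contours(m, min_area = 5)
  cand <- extract_candidates_top(cts, base_anchor("top", 11, 5))
  expect_equal(nrow(cand), 2)
  expect_equal(cand$contour_id, c(1, 2))
  expect_equal(cand$v[1], 39)  # far end of the bar (rows 10:40 -> v 9..39)
  # every candidate is a foreground pixel
  for (i in seq_len(nrow(cand)))
    expect_equal(m[cand$v[i] + 1, cand$u[i] + 1], 1L)
  # max_candidates caps the list
  expect_equal(nrow(extract_candidates_top(cts, base_anchor("top", 11, 5),
                                           max_candidates = 1L)), 1)
})

test_that("epipolar lines are normalized and pass through correspondences", {
  cfg <- scene_config()
  cams <- true_cameras(cfg)
  rel <- relative_pose(cams$top$pose, cams$side$pose)
  rig <- stereo_rig(cams$top, cams$side, rel$R_rel, rel$t_rel)
  pts <- make_trajectory(cfg, 25)
  pt <- project_points(cams$top, pts); ps <- project_points(cams$side, pts)
  for (i in seq_len(nrow(pts))) {
    l <- epipolar_line(rig$F, pt[i, ])
    expect_equal(l[1]^2 + l[2]^2, 1, tolerance = 1e-12)
    expect_lt(abs(sum(l * c(ps[i, ], 1))), 1e-6)
  }
})

test_that("epipolar lines form a pencil through the side epipole", {
  cfg <- scene_config()
  cams <- true_cameras(cfg)
  rel <- relative_pose(cams$top$pose, cams$side$pose)
  rig <- stereo_rig(cams$top, cams$side, rel$R_rel, rel$t_rel)
  cross2 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  # side lines of any top pixels intersect in one point: the side epipole
  ls <- lapply(list(c(300, 200), c(700, 500), c(1000, 250)),
               function(p) epipolar_line(rig$F, p))
  e12 <- cross2(ls[[1]], ls[[2]]); e12 <- e12 / e12[3]
  e13 <- cross2(ls[[1]], ls[[3]]); e13 <- e13 / e13[3]
  expect_equal(e12, e13, tolerance = 1e-6)
  # and that point is the null vector of F' (the image of the top camera)
  expect_lt(max(abs(t(rig$F) %*% e12)) / norm(rig$F, "F"), 1e-6)
  # a pixel moved along its own epipolar line keeps the same side line
  # (the degenerate member of the pencil: such pixels are collinear with
  # the top epipole)
  lt <- epipolar_line(t(rig$F), c(700, 300))
  p0 <- c(500, -(lt[3] + lt[1] * 500) / lt[2])
  p1 <- c(900, -(lt[3] + lt[1] * 900) / lt[2])
  l0 <- epipolar_line(rig$F, p0); l1 <- epipolar_line(rig$F, p1)
  expect_equal(abs(l0), abs(l1), tolerance = 1e-6)
})

test_that("fragment selection keeps contours near the line with a fallback", {
  mk <- function(u0, v0) list(id = 1, area = 9,
                              pixels = as.matrix(expand.grid(u = u0 + 0:2,
                                                             v = v0 + 0:2)))
  line <- c(0, 1, -50)  # horizontal line v = 50
  near <- mk(10, 48); far <- mk(10, 110)
  expect_equal(length(select_fragments_near_line(list(near), line, 20)), 1)
  sel <- select_fragments_near_line(list(near, far), line, 20)
  expect_equal(length(sel), 1)
  expect_equal(unname(sel[[1]]$pixels[1, 2]), 48)
  # all beyond threshold: exactly the closest survives
  sel2 <- select_fragments_near_line(list(mk(10, 100), mk(10, 80)), line, 5)
  expect_equal(length(sel2), 1)
  expect_equal(unname(sel2[[1]]$pixels[1, 2]), 80)
})

test_that("side-view candidates follow the epipolar-guided composition", {
  cfg <- scene_config()
  cams <- true_cameras(cfg)
  rel <- relative_pose(cams$top$pose, cams$side$pose)
  rig <- stereo_rig(cams$top, cams$side, rel$R_rel, rel$t_rel)
  tip <- c(6, 3, 45)
  fr <- render_frame(cfg, cams, tip, 1, noise = FALSE)
  mask <- matrix(as.integer(fr$side < 75), nrow(fr$side), ncol(fr$side))
  cts <- extract_contours(mask, min_area = 20)
  bs <- project_points(cams$side, c(0, 0, 10))
  line <- epipolar_line(rig$F, project_points(cams$top, tip))
  cand <- extract_candidates_side(cts, base_anchor("side", bs[1], bs[2]), line)
  expect_equal(nrow(cand), 1)
  true_side <- project_points(cams$side, tip)
  expect_lt(sqrt((cand$u - true_side[1])^2 + (cand$v - true_side[2])^2), 3)
  # without a line all fragments are considered
  cand2 <- extract_candidates_side(cts, base_anchor("side", bs[1], bs[2]), NULL)
  expect_equal(nrow(cand2), length(cts))
  # every candidate lies on the segmented contour
  for (i in seq_len(nrow(cand2)))
    expect_equal(mask[cand2$v[i] + 1, cand2$u[i] + 1], 1L)
})
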