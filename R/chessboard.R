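# Chessboard corner detection for calibration images.
#
# Inner corners of a chessboard are intensity saddle points; the detector
# scores pixels by the negated determinant of the smoothed Hessian (positive
# at saddles, negative at light/dark blob corners, ~0 on straight edges),
# takes non-maximum-suppressed peaks, fits a projective grid through them to
# establish the canonical row-major ordering, and refines each corner to
# sub-pixel accuracy by quadratic peak interpolation of the response.

#' Chessboard geometry
#'
#' @param inner_cols,inner_rows Number of inner corners along each direction
#'   (a board of (inner_cols+1) x (inner_rows+1) squares).
#' @param square_size Side of one square in cm.
#' @return An object of class `board_spec`.
#' @export
board_spec <- function(inner_cols, inner_rows, square_size) {
  stopifnot(inner_cols >= 2, inner_rows >= 2, square_size > 0)
  structure(list(inner_cols = as.integer(inner_cols),
                 inner_rows = as.integer(inner_rows),
                 square_size = square_size),
            class = "board_spec")
}

#' Board-frame coordinates of the inner corners
#'
#' Row-major from the origin corner: index runs over columns fastest.
#' The board plane is Z = 0.
#'
#' @param spec A [board_spec()].
#' @return N x 3 matrix of corner positions (cm), N = inner_cols * inner_rows.
#' @export
board_object_points <- function(spec) {
  g <- expand.grid(gi = 0:(spec$inner_cols - 1), gj = 0:(spec$inner_rows - 1))
  cbind(g$gi * spec$square_size, g$gj * spec$square_size, 0)
}

# exact homography from >= 4 point correspondences (normalized DLT)
homography_dlt <- function(src, dst) {
  stopifnot(nrow(src) >= 4, nrow(src) == nrow(dst))
  norm_pts <- function(p) {
    mu <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * mu[1], -s * mu[2], 1), 3, 3)
    list(T = T, p = cbind(s * (p[, 1] - mu[1]), s * (p[, 2] - mu[2])))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  n <- length(x)
  A <- rbind(
    cbind(-x, -y, -1, 0 * x, 0 * x, 0 * x, u * x, u * y, u),
    cbind(0 * x, 0 * x, 0 * x, -x, -y, -1, v * x, v * y, v))
  # null vector of A: smallest eigenvector of A'A (A may be 8 x 9 for n = 4)
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- solve(nd$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% ns$T
  H / H[3, 3]
}

apply_homography <- function(H, p) {
  q <- cbind(p, 1) %*% t(H)
  cbind(q[, 1] / q[, 3], q[, 2] / q[, 3])
}

# saddle response: -det(Hessian) of the blurred image
corner_response <- function(img, sigma = 1.5) {
  s <- gauss_blur(img, sigma)
  iu <- deriv_img(s, "u"); iv <- deriv_img(s, "v")
  iuu <- deriv_img(iu, "u"); ivv <- deriv_img(iv, "v"); iuv <- deriv_img(iu, "v")
  iuv^2 - iuu * ivv
}

# local maxima of resp above thr within a (2w+1)^2 window, as row/col indices
nms_peaks <- function(resp, w = 4L, thr) {
  nr <- nrow(resp); nc <- ncol(resp)
  dil <- resp
  for (o in seq_len(w)) {
    dil <- pmax(dil,
                rbind(matrix(-Inf, o, nc), dil[seq_len(nr - o), , drop = FALSE]),
                rbind(dil[(o + 1):nr, , drop = FALSE], matrix(-Inf, o, nc)))
  }
  for (o in seq_len(w)) {
    dil <- pmax(dil,
                cbind(matrix(-Inf, nr, o), dil[, seq_len(nc - o), drop = FALSE]),
                cbind(dil[, (o + 1):nc, drop = FALSE], matrix(-Inf, nr, o)))
  }
  which(resp >= dil & resp > thr, arr.ind = TRUE)
}

# sub-pixel corner: stationary (saddle) point of a local quadratic fit to
# the blurred intensity; the saddle of a symmetrically blurred X-corner sits
# exactly on the corner
refine_saddle <- function(simg, r, c, halfwin = 2L) {
  nr <- nrow(simg); nc <- ncol(simg)
  if (r <= halfwin + 1 || r > nr - halfwin - 1 ||
      c <= halfwin + 1 || c > nc - halfwin - 1)
    return(c(c - 1, r - 1))
  w <- (-halfwin):halfwin
  g <- expand.grid(y = w, x = w)
  X <- cbind(1, g$x, g$y, g$x^2, g$x * g$y, g$y^2)
  XtXi_Xt <- solve(crossprod(X), t(X))
  u <- c - 1; v <- r - 1  # 0-based running estimate
  for (iter in 1:3) {
    z <- bilinear_patch(simg, v, u, g$y, g$x)
    if (is.null(z)) break
    b <- XtXi_Xt %*% z
    H <- matrix(c(2 * b[4], b[5], b[5], 2 * b[6]), 2, 2)
    delta <- tryCatch(-solve(H, c(b[2], b[3])), error = function(e) c(0, 0))
    if (any(!is.finite(delta))) delta <- c(0, 0)
    delta <- pmin(pmax(delta, -1), 1)
    u <- u + delta[1]; v <- v + delta[2]
    if (max(abs(delta)) < 1e-3) break
  }
  c(min(max(u, c - 2), c), min(max(v, r - 2), r))
}

# bilinear samples of img at 0-based (v + dy, u + dx); NULL when out of range
bilinear_patch <- function(img, v, u, dy, dx) {
  y <- v + dy + 1; x <- u + dx + 1
  if (min(y) < 1 || max(y) > nrow(img) - 1 || min(x) < 1 || max(x) > ncol(img) - 1)
    return(NULL)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fy) * (1 - fx) + img[i01] * (1 - fy) * fx +
    img[i10] * fy * (1 - fx) + img[i11] * fy * fx
}

# 2D quadratic peak interpolation of resp around integer peak (r, c)
refine_peak <- function(resp, r, c) {
  nr <- nrow(resp); nc <- ncol(resp)
  if (r < 2 || r > nr - 1 || c < 2 || c > nc - 1) return(c(c - 1, r - 1))
  z <- resp[(r - 1):(r + 1), (c - 1):(c + 1)]
  dx <- (z[2, 3] - z[2, 1]) / 2; dy <- (z[3, 2] - z[1, 2]) / 2
  dxx <- z[2, 3] - 2 * z[2, 2] + z[2, 1]
  dyy <- z[3, 2] - 2 * z[2, 2] + z[1, 2]
  dxy <- (z[3, 3] - z[3, 1] - z[1, 3] + z[1, 1]) / 4
  H <- matrix(c(dxx, dxy, dxy, dyy), 2, 2)
  delta <- tryCatch(-solve(H, c(dx, dy)), error = function(e) c(0, 0))
  delta <- pmin(pmax(delta, -1), 1)
  c(c - 1 + delta[1], r - 1 + delta[2])  # (u, v), 0-based
}

# try to order candidate corners (m x 2, (u,v), m >= cols*rows) as a
# cols x rows grid; returns integer index vector (row-major) or NULL
fit_grid <- function(pts, cols, rows, img = NULL) {
  n <- cols * rows
  if (nrow(pts) < n) return(NULL)
  hull <- grDevices::chull(pts)
  if (length(hull) < 4) return(NULL)
  # 4 hull vertices spanning the largest quadrilateral
  best <- NULL; best_area <- -1
  combs <- utils::combn(hull, 4L)
  quad_area <- function(q) {
    p <- pts[q, , drop = FALSE]
    abs(sum(p[, 1] * p[c(2:4, 1), 2] - p[c(2:4, 1), 1] * p[, 2])) / 2
  }
  for (j in seq_len(ncol(combs))) {
    a <- quad_area(combs[, j])
    if (a > best_area) { best_area <- a; best <- combs[, j] }
  }
  corners <- pts[best, , drop = FALSE]  # in hull (ccw) order
  grid_corners <- rbind(c(0, 0), c(cols - 1, 0), c(cols - 1, rows - 1), c(0, rows - 1))
  candidates <- list()
  for (rot in 0:3) {
    for (dir in c(1, -1)) {
      idx <- if (dir == 1) ((0:3 + rot) %% 4) + 1 else ((3:0 + rot) %% 4) + 1
      H <- tryCatch(homography_dlt(grid_corners, corners[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H)) next
      # map all candidates to grid coordinates and snap; every cell must be
      # covered, the best-fitting candidate claiming each cell
      Hi <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(Hi)) next
      g <- apply_homography(Hi, pts)
      gr <- round(g)
      dev <- pmax(abs(g[, 1] - gr[, 1]), abs(g[, 2] - gr[, 2]))
      ok <- dev <= 0.35 & gr[, 1] >= 0 & gr[, 1] <= cols - 1 &
        gr[, 2] >= 0 & gr[, 2] <= rows - 1
      if (sum(ok) < n) next
      key <- gr[ok, 1] + cols * gr[ok, 2]
      idx <- which(ok)[order(key, dev[ok])]
      key <- sort(key)
      sel <- idx[!duplicated(key)]
      if (length(sel) != n) next
      ord <- sel[order(gr[sel, 1] + cols * gr[sel, 2])]
      candidates[[length(candidates) + 1]] <- list(ord = ord, H = H)
    }
  }
  if (!length(candidates)) return(NULL)
  if (length(candidates) > 1) {
    # facing the front of a right-handed board, the grid-to-image mapping
    # reverses orientation (image v runs downward); mirrored assignments
    # (back-view interpretations) have the opposite sign and drop out
    ori <- vapply(candidates, function(cand) homography_orientation(cand$H),
                  numeric(1))
    if (any(ori < 0)) candidates <- candidates[ori < 0]
  }
  if (!is.null(img) && length(candidates) > 1) {
    # remaining 180-degree ambiguity: the square diagonally up-left of the
    # origin corner (board square 0,0) is black
    dark <- sample_square_dark(candidates, img)
    if (any(dark)) candidates <- candidates[dark]
  }
  candidates[[1]]$ord
}

# sign of the Jacobian determinant of H at the grid center
homography_orientation <- function(H, at = c(4, 2.5)) {
  p <- apply_homography(H, rbind(at, at + c(1e-3, 0), at + c(0, 1e-3)))
  a <- p[2, ] - p[1, ]; b <- p[3, ] - p[1, ]
  sign(a[1] * b[2] - a[2] * b[1])
}

sample_square_dark <- function(candidates, img) {
  vapply(candidates, function(cand) {
    ctr <- apply_homography(cand$H, matrix(c(-0.5, -0.5), 1, 2))
    r <- round(ctr[2]) + 1L; c <- round(ctr[1]) + 1L
    if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img)) return(FALSE)
    img[r, c] < mean(range(img))
  }, logical(1))
}

#' Detect a full chessboard grid in a grayscale image
#'
#' Finds all inner corners, orders them canonically (row-major from a fixed
#' physical corner, stable under in-plane board rotation) and refines them to
#' sub-pixel accuracy. A partial grid yields `NULL`, never a truncated
#' observation.
#'
#' @param image Numeric matrix (rows = image v axis), any intensity scale.
#' @param spec A [board_spec()].
#' @param frame_id Identifier stored in the observation.
#' @param sigma Smoothing scale in pixels for the corner response.
#' @return A `board_observation` (list with `image_points` N x 2 pixel
#'   matrix, `object_points` N x 3 board-frame matrix, `frame_id`), or `NULL`
#'   if the full grid is not found.
#' @export
detect_chessboard <- function(image, spec, frame_id = NA, sigma = 1.5) {
  rng <- range(image)
  if (diff(rng) <= 0) return(NULL)
  img <- (image - rng[1]) / diff(rng)
  resp <- corner_response(img, sigma)
  n <- spec$inner_cols * spec$inner_rows
  peaks <- nms_peaks(resp, w = 4L, thr = max(resp) * 0.08)
  if (nrow(peaks) < n) return(NULL)
  vals <- resp[peaks]
  o <- order(vals, decreasing = TRUE)
  peaks <- peaks[o, , drop = FALSE]; vals <- vals[o]
  # merge plateau duplicates (two peaks of one corner), strongest first
  kept <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    if (!length(kept) ||
        min((peaks[kept, 1] - peaks[i, 1])^2 +
              (peaks[kept, 2] - peaks[i, 2])^2) > 16) kept <- c(kept, i)
    if (length(kept) >= n + 8L) break
  }
  peaks <- peaks[kept, , drop = FALSE]; vals <- vals[kept]
  if (nrow(peaks) < n) return(NULL)
  # drop candidates much weaker than the n-th strongest (edge artifacts)
  sel <- vals >= vals[n] * 0.5
  peaks <- peaks[sel, , drop = FALSE]
  simg <- gauss_blur(img, sigma)
  uv <- t(vapply(seq_len(nrow(peaks)),
                 function(i) refine_saddle(simg, peaks[i, 1], peaks[i, 2]),
                 numeric(2)))
  ord <- fit_grid(uv, spec$inner_cols, spec$inner_rows, img)
  if (is.null(ord)) return(NULL)
  structure(list(image_points = uv[ord, , drop = FALSE],
                 object_points = board_object_points(spec),
                 frame_id = frame_id),
            class = "board_observation")
}
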