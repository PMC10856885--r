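#' @useDynLib stereonut, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median quantile approx
#' @importFrom utils read.csv write.csv
NULL

# ---- constructors -----------------------------------------------------------

#' Camera intrinsic parameters
#'
#' Focal lengths and principal point in pixel units, plus the image size.
#' The pixel coordinate convention is origin at the top-left, u rightward,
#' v downward, with pixel centers at integer coordinates.
#'
#' @param fx,fy Focal lengths in pixel units (positive).
#' @param cx,cy Principal point in pixels; must lie inside the image.
#' @param width,height Image size in pixels.
#' @return An object of class `intrinsics`.
#' @export
intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0,
            cx >= 0, cx < width, cy >= 0, cy < height)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "intrinsics")
}

#' Lens distortion coefficients
#'
#' Radial (k1, k2, k3) and tangential (p1, p2) coefficients acting on
#' normalized image coordinates. All default to zero (ideal pinhole).
#'
#' @param k1,k2,k3 Radial coefficients (dimensionless).
#' @param p1,p2 Tangential coefficients (dimensionless).
#' @return An object of class `distortion`.
#' @export
distortion <- function(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  v <- c(k1, k2, k3, p1, p2)
  stopifnot(all(is.finite(v)))
  structure(list(k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
            class = "distortion")
}

#' Rigid camera pose (world to camera)
#'
#' @param R 3x3 rotation matrix mapping world to camera coordinates.
#'   Orthonormality and det(R) = +1 are checked to 1e-9 at construction.
#' @param t Length-3 translation in world length units (cm).
#' @return An object of class `pose`.
#' @export
pose <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("pose rotation is not orthonormal (RtR != I beyond 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    stop("pose rotation must have det(R) = +1")
  structure(list(R = R, t = t), class = "pose")
}

#' Full camera model
#'
#' Bundles intrinsics, distortion and pose into the projective model
#' s p = A [R|t] Pw with radial/tangential distortion applied between
#' the normalization and pixel-mapping steps.
#'
#' @param intrinsics An [intrinsics()] object.
#' @param distortion A [distortion()] object (defaults to zero distortion).
#' @param pose A [pose()] object (defaults to the identity pose).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(intrinsics, distortion = NULL, pose = NULL) {
  stopifnot(inherits(intrinsics, "intrinsics"))
  if (is.null(distortion)) distortion <- stereonut::distortion()
  if (is.null(pose)) pose <- stereonut::pose()
  stopifnot(inherits(distortion, "distortion"), inherits(pose, "pose"))
  structure(list(intrinsics = intrinsics, distortion = distortion, pose = pose),
            class = "camera_model")
}

#' Intrinsic parameter matrix A
#' @param intr An [intrinsics()] object.
#' @return The 3x3 upper-triangular intrinsic matrix.
#' @export
intrinsic_matrix <- function(intr) {
  matrix(c(intr$fx, 0, 0, 0, intr$fy, 0, intr$cx, intr$cy, 1), 3, 3)
}

as_point_matrix <- function(p, d) {
  if (is.null(dim(p))) p <- matrix(p, ncol = d, byrow = FALSE)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == d)
  p
}

# ---- geometry ---------------------------------------------------------------

#' Transform world points into the camera frame
#'
#' Applies the change of basis pc = R pw + t.
#'
#' @param pose A [pose()] object.
#' @param pw 3-vector or N x 3 matrix of world points (cm).
#' @return N x 3 matrix of points in the camera frame (cm).
#' @export
world_to_camera <- function(pose, pw) {
  pw <- as_point_matrix(pw, 3)
  sweep(pw %*% t(pose$R), 2, pose$t, "+")
}

#' Camera center in world coordinates
#' @param pose A [pose()] object.
#' @return 3-vector, the optical center -R't (cm).
#' @export
camera_center <- function(pose) as.numeric(-crossprod(pose$R, pose$t))

#' Apply lens distortion to normalized image coordinates
#'
#' Radial: x(1 + k1 r^2 + k2 r^4 + k3 r^6); tangential: added term
#' p2 (r^2 + 2 x^2) + 2 p1 x y for x, and p1 (r^2 + 2 y^2) + 2 p2 x y for y,
#' with r^2 = x^2 + y^2.
#'
#' @param d A [distortion()] object.
#' @param xy 2-vector or N x 2 matrix of undistorted normalized coordinates.
#' @return N x 2 matrix of distorted normalized coordinates.
#' @export
apply_distortion <- function(d, xy) {
  xy <- as_point_matrix(xy, 2)
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
  cbind(x * radial + d$p2 * (r2 + 2 * x^2) + 2 * d$p1 * x * y,
        y * radial + d$p1 * (r2 + 2 * y^2) + 2 * d$p2 * x * y)
}

#' Invert lens distortion by fixed-point iteration
#'
#' Solves apply_distortion(d, x) = xy_dist for x. Intended for moderate
#' distortion (correction below 0.5 in normalized units); iterates at most
#' `max_iter` times and fails with the residual if the tolerance is not met.
#'
#' @param d A [distortion()] object.
#' @param xy_dist 2-vector or N x 2 matrix of distorted normalized coords.
#' @param tol Convergence tolerance on the forward residual (normalized units).
#' @param max_iter Iteration cap.
#' @return N x 2 matrix of undistorted normalized coordinates.
#' @export
remove_distortion <- function(d, xy_dist, tol = 1e-10, max_iter = 50L) {
  xy_dist <- as_point_matrix(xy_dist, 2)
  xd <- xy_dist[, 1]; yd <- xy_dist[, 2]
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
    x_new <- (xd - (d$p2 * (r2 + 2 * x^2) + 2 * d$p1 * x * y)) / radial
    y_new <- (yd - (d$p1 * (r2 + 2 * y^2) + 2 * d$p2 * x * y)) / radial
    delta <- max(abs(x_new - x), abs(y_new - y))
    x <- x_new; y <- y_new
    if (delta < tol) break
  }
  res <- apply_distortion(d, cbind(x, y)) - xy_dist
  resid <- max(abs(res))
  if (resid > 100 * tol)
    stop(sprintf("distortion inversion did not converge (residual %.3g)", resid))
  cbind(x, y)
}

#' Project world points to pixel coordinates
#'
#' Composes world-to-camera transform, perspective normalization, lens
#' distortion and the intrinsic pixel mapping u = fx x' + cx, v = fy y' + cy.
#'
#' @param cam A [camera_model()] object.
#' @param pw 3-vector or N x 3 matrix of world points (cm); all must lie in
#'   front of the camera (Zc > 0).
#' @return N x 2 matrix of pixel coordinates (u, v).
#' @export
project_points <- function(cam, pw) {
  pc <- world_to_camera(cam$pose, pw)
  if (any(pc[, 3] <= 0))
    stop("point behind camera (Zc <= 0) cannot be projected")
  xy <- cbind(pc[, 1] / pc[, 3], pc[, 2] / pc[, 3])
  xyd <- apply_distortion(cam$distortion, xy)
  intr <- cam$intrinsics
  cbind(intr$fx * xyd[, 1] + intr$cx, intr$fy * xyd[, 2] + intr$cy)
}

#' Map pixels to undistorted normalized image coordinates
#'
#' @param cam A [camera_model()] object.
#' @param uv 2-vector or N x 2 matrix of pixel coordinates.
#' @return N x 2 matrix of undistorted normalized coordinates.
#' @export
pixel_to_normalized <- function(cam, uv) {
  uv <- as_point_matrix(uv, 2)
  intr <- cam$intrinsics
  xyd <- cbind((uv[, 1] - intr$cx) / intr$fx, (uv[, 2] - intr$cy) / intr$fy)
  remove_distortion(cam$distortion, xyd)
}

# ---- rotation helpers -------------------------------------------------------

#' Rodrigues rotation vector to matrix
#' @param rvec Length-3 rotation vector (axis times angle, radians).
#' @return 3x3 rotation matrix.
#' @export
rodrigues_to_matrix <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th < 1e-12) return(diag(3))
  k <- rvec / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to Rodrigues vector
#' @param R 3x3 rotation matrix.
#' @return Length-3 rotation vector.
#' @export
matrix_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near-pi: extract axis from R + I
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    i <- which.max(axis)
    if (axis[i] > 0) {
      axis <- B[, i] / axis[i]
      axis <- axis / sqrt(sum(axis^2))
    }
    return(axis * th)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(th)) * th
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# ---- serialization ----------------------------------------------------------

camera_to_list <- function(cam) {
  list(fx = cam$intrinsics$fx, fy = cam$intrinsics$fy,
       cx = cam$intrinsics$cx, cy = cam$intrinsics$cy,
       width = cam$intrinsics$width, height = cam$intrinsics$height,
       k1 = cam$distortion$k1, k2 = cam$distortion$k2, k3 = cam$distortion$k3,
       p1 = cam$distortion$p1, p2 = cam$distortion$p2,
       R = as.numeric(t(cam$pose$R)),  # row-major
       t = as.numeric(cam$pose$t))
}

camera_from_list <- function(x) {
  camera_model(
    intrinsics(x$fx, x$fy, x$cx, x$cy, x$width, x$height),
    distortion(x$k1, x$k2, x$k3, x$p1, x$p2),
    pose(t(matrix(as.numeric(x$R), 3, 3)), as.numeric(x$t)))
}

#' Write a camera model to YAML
#'
#' Scalar keys fx, fy, cx, cy, width, height, k1, k2, k3, p1, p2; R as nine
#' row-major values; t as three values. Doubles are written with 17
#' significant digits so the round-trip is bit-exact.
#'
#' @param cam A [camera_model()] object.
#' @param path Output file path.
#' @export
write_camera_yaml <- function(cam, path) {
  writeLines(yaml::as.yaml(camera_to_list(cam), precision = 17L), path)
  invisible(path)
}

#' Read a camera model written by [write_camera_yaml()]
#' @param path Input file path.
#' @return A [camera_model()] object.
#' @export
read_camera_yaml <- function(path) {
  camera_from_list(yaml::yaml.load_file(path))
}

#' @export
print.camera_model <- function(x, ...) {
  i <- x$intrinsics
  cat(sprintf("camera_model %dx%d  fx=%.3f fy=%.3f cx=%.3f cy=%.3f\n",
              i$width, i$height, i$fx, i$fy, i$cx, i$cy))
  d <- x$distortion
  cat(sprintf("  distortion k=(%.4g, %.4g, %.4g) p=(%.4g, %.4g)\n",
              d$k1, d$k2, d$k3, d$p1, d$p2))
  cat("  center (cm):", sprintf("%.3f", camera_center(x$pose)), "\n")
  invisible(x)
}
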