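# small raster helpers shared by chessboard detection, segmentation and the
# synthetic renderer; images are numeric matrices [row = v + 1, col = u + 1]
# with 0-based pixel centers at integer (u, v)

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicate padding
gauss_blur <- function(img, sigma) {
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    o <- i - r - 1L
    out <- out + k[i] * img[pmin(pmax(seq_len(nr) + o, 1L), nr), , drop = FALSE]
  }
  img <- out
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    o <- i - r - 1L
    out <- out + k[i] * img[, pmin(pmax(seq_len(nc) + o, 1L), nc), drop = FALSE]
  }
  out
}

# central-difference derivative along rows (v) or cols (u), replicate edges
deriv_img <- function(img, dim = c("u", "v")) {
  dim <- match.arg(dim)
  nr <- nrow(img); nc <- ncol(img)
  if (dim == "u") {
    (img[, pmin(seq_len(nc) + 1L, nc), drop = FALSE] -
       img[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]) / 2
  } else {
    (img[pmin(seq_len(nr) + 1L, nr), , drop = FALSE] -
       img[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]) / 2
  }
}

# binary dilation/erosion with a (2r+1)^2 square structuring element
dilate_bin <- function(m, r = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (o in seq_len(r)) {
    out <- pmax(out,
                rbind(matrix(0L, o, nc), out[seq_len(nr - o), , drop = FALSE]),
                rbind(out[(o + 1):nr, , drop = FALSE], matrix(0L, o, nc)))
  }
  for (o in seq_len(r)) {
    out <- pmax(out,
                cbind(matrix(0L, nr, o), out[, seq_len(nc - o), drop = FALSE]),
                cbind(out[, (o + 1):nc, drop = FALSE], matrix(0L, nr, o)))
  }
  out
}

erode_bin <- function(m, r = 1L) 1L - dilate_bin(1L - m, r)

# morphological closing: bridges small gaps between nearby fragments
morph_close <- function(m, r = 1L) erode_bin(dilate_bin(m, r), r)

# pixel (u, v) [0-based] of matrix entry; and back
rc_to_uv <- function(rc) cbind(u = rc[, 2] - 1, v = rc[, 1] - 1)
uv_to_rc <- function(uv) cbind(row = round(uv[, 2]) + 1L, col = round(uv[, 1]) + 1L)
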