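# Per-frame plant-tip candidate extraction.
#
# Top view: for each retained contour, the candidate is the foreground pixel
# with the greatest geodesic (within-mask shortest-path) distance from the
# contour pixel nearest the plant-base anchor. Side view: the epipolar line
# of the top-view tip first selects the contour fragment(s) likely to hold
# the tip, then the same minimum-path rule localizes the candidate inside
# each fragment. Path costs are 1 (axial) and sqrt(2) (diagonal) on the
# 8-connected pixel graph.

#' Plant-base anchor for one view
#'
#' Pixel of the pot base in a view, against which geodesic tip distances are
#' measured (shown as the green dot in trajectory plots).
#'
#' @param view `"top"` or `"side"`.
#' @param u,v Pixel coordinates (0-based).
#' @return An object of class `base_anchor`.
#' @export
base_anchor <- function(view = c("top", "side"), u, v) {
  view <- match.arg(view)
  stopifnot(is.finite(u), is.finite(v), u >= 0, v >= 0)
  structure(list(view = view, pixel = c(u = u, v = v)), class = "base_anchor")
}

empty_candidates <- function(frame_id, view) {
  structure(data.frame(u = numeric(0), v = numeric(0),
                       contour_id = integer(0), geodesic_score = numeric(0)),
            frame_id = frame_id, view = view, class = c("candidate_set", "data.frame"))
}

candidate_set <- function(df, frame_id, view) {
  structure(df, frame_id = frame_id, view = view,
            class = c("candidate_set", "data.frame"))
}

# geodesic distances over one fragment; source = fragment pixel nearest `from_uv`
fragment_geodesic <- function(pixels, from_uv) {
  u <- pixels[, 1]; v <- pixels[, 2]
  u0 <- min(u); v0 <- min(v)
  nr <- max(v) - v0 + 1L; nc <- max(u) - u0 + 1L
  m <- matrix(0L, nr, nc)
  m[cbind(v - v0 + 1L, u - u0 + 1L)] <- 1L
  src <- which.min((u - from_uv[1])^2 + (v - from_uv[2])^2)
  d <- geodesic_cpp(m, v[src] - v0 + 1L, u[src] - u0 + 1L)
  list(dist = d[cbind(v - v0 + 1L, u - u0 + 1L)], source = src)
}

#' Locate the tip candidate of one mask fragment by minimum path
#'
#' Runs a single-source shortest path from the fragment pixel nearest the
#' base anchor and returns the pixel at maximal geodesic distance. Ties are
#' broken toward larger v (lower in the image), then larger u.
#'
#' @param pixels N x 2 matrix of 0-based (u, v) foreground pixels of one
#'   8-connected fragment.
#' @param base A [base_anchor()] (or length-2 pixel vector).
#' @return List with `pixel` (c(u, v)), `score` (geodesic distance in px)
#'   and `source` (the pixel the path starts from).
#' @export
min_path_tip <- function(pixels, base) {
  stopifnot(nrow(pixels) >= 1)
  from <- if (inherits(base, "base_anchor")) base$pixel else base
  g <- fragment_geodesic(pixels, from)
  d <- g$dist
  reach <- which(is.finite(d))
  dmax <- max(d[reach])
  cand <- reach[d[reach] >= dmax - 1e-9]
  cand <- cand[order(pixels[cand, 2], pixels[cand, 1], decreasing = TRUE)][1]
  list(pixel = c(u = unname(pixels[cand, 1]), v = unname(pixels[cand, 2])),
       score = unname(d[cand]),
       source = c(u = unname(pixels[g$source, 1]), v = unname(pixels[g$source, 2])))
}

#' Extract top-view tip candidates from segmented contours
#'
#' One candidate per retained contour (the geodesic-farthest pixel from the
#' base), at most `max_candidates`, ranked by contour area.
#'
#' @param contours Contour list from [extract_contours()] (noise-filtered).
#' @param base A [base_anchor()] for the top view.
#' @param max_candidates Cap on returned candidates.
#' @param frame_id Identifier stored on the candidate set.
#' @return A `candidate_set` data frame (columns u, v, contour_id,
#'   geodesic_score); empty when no contours remain.
#' @export
extract_candidates_top <- function(contours, base, max_candidates = 5L,
                                   frame_id = NA) {
  if (!length(contours)) return(empty_candidates(frame_id, "top"))
  contours <- contours[seq_len(min(length(contours), max_candidates))]
  rows <- lapply(contours, function(ct) {
    tip <- min_path_tip(ct$pixels, base)
    data.frame(u = tip$pixel[["u"]], v = tip$pixel[["v"]],
               contour_id = ct$id, geodesic_score = tip$score)
  })
  candidate_set(do.call(rbind, rows), frame_id, "top")
}

#' Epipolar line in the side view of a top-view pixel
#'
#' @param F Fundamental matrix (top to side convention).
#' @param p_top Length-2 pixel (u, v) in the top view.
#' @return Coefficients c(a, b, c) with a^2 + b^2 = 1; the distance of side
#'   pixel (u, v) from the line is |a u + b v + c|.
#' @export
epipolar_line <- function(F, p_top) {
  l <- as.numeric(F %*% c(p_top[1], p_top[2], 1))
  nrm <- sqrt(l[1]^2 + l[2]^2)
  if (nrm < 1e-12 * max(1, abs(l[3])))
    stop("degenerate epipolar line: pixel coincides with the epipole")
  l / nrm
}

point_line_distance <- function(line, uv) {
  abs(line[1] * uv[, 1] + line[2] * uv[, 2] + line[3])
}

#' Select contour fragments near an epipolar line
#'
#' Keeps fragments whose minimum point-to-line distance is within
#' `dist_threshold`; when none qualify, the single closest fragment is kept
#' so a candidate always exists while the plant is segmented.
#'
#' @param contours Contour list from [extract_contours()].
#' @param line Normalized line coefficients from [epipolar_line()].
#' @param dist_threshold Distance cutoff in pixels.
#' @return Subset of `contours`.
#' @export
select_fragments_near_line <- function(contours, line, dist_threshold = 20) {
  if (!length(contours)) return(contours)
  dmin <- vapply(contours, function(ct) min(point_line_distance(line, ct$pixels)),
                 numeric(1))
  keep <- dmin <= dist_threshold
  if (!any(keep)) keep <- seq_along(contours) == which.min(dmin)
  contours[keep]
}

#' Extract side-view tip candidates
#'
#' Epipolar fragment selection followed by per-fragment minimum-path tip
#' localization. When no top-view tip (hence no epipolar line) is available
#' for the frame, all fragments are considered.
#'
#' @param contours Contour list from [extract_contours()].
#' @param base A [base_anchor()] for the side view.
#' @param line Epipolar line from [epipolar_line()], or `NULL`.
#' @param dist_threshold Epipolar distance cutoff in pixels.
#' @param max_candidates Cap on returned candidates.
#' @param frame_id Identifier stored on the candidate set.
#' @return A `candidate_set` data frame.
#' @export
extract_candidates_side <- function(contours, base, line = NULL,
                                    dist_threshold = 20, max_candidates = 5L,
                                    frame_id = NA) {
  if (!length(contours)) return(empty_candidates(frame_id, "side"))
  if (!is.null(line)) contours <- select_fragments_near_line(contours, line, dist_threshold)
  contours <- contours[seq_len(min(length(contours), max_candidates))]
  rows <- lapply(contours, function(ct) {
    tip <- min_path_tip(ct$pixels, base)
    data.frame(u = tip$pixel[["u"]], v = tip$pixel[["v"]],
               contour_id = ct$id, geodesic_score = tip$score)
  })
  candidate_set(do.call(rbind, rows), frame_id, "side")
}
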