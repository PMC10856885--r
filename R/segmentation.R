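# Gaussian-mixture background segmentation with lighting-change handling.
#
# Each pixel keeps up to `max_components` Gaussian modes of its grayscale
# intensity. A frame pixel is background when it matches one of the
# highest-weight modes whose cumulative weight stays within
# `background_threshold`. Global lighting steps (photoperiod transitions)
# flood the foreground; when the total contour area crosses
# `lighting_change_area` the model is reset from the current frame, and
# re-detection is suppressed for `lighting_change_est_time` frames.

#' Create a mixture-of-Gaussians background model
#'
#' @param width,height Frame size in pixels.
#' @param max_components Gaussian modes per pixel.
#' @param learning_rate Per-frame update fraction (alpha).
#' @param background_threshold Cumulative-weight fraction defining the
#'   background modes.
#' @param var_threshold Squared-Mahalanobis matching cutoff (16 ~ 4 sigma).
#' @param var_floor Lower bound on mode variance (intensity^2, 0-255 scale).
#' @param init_var Variance assigned to newly created modes.
#' @return An environment of class `mog_model` holding the per-pixel state.
#' @export
mog_model <- function(width, height, max_components = 5L,
                      learning_rate = 0.01, background_threshold = 0.9,
                      var_threshold = 16, var_floor = 1, init_var = 25) {
  stopifnot(width > 0, height > 0, max_components >= 1,
            learning_rate > 0, learning_rate < 1)
  n <- as.integer(width) * as.integer(height)
  K <- as.integer(max_components)
  m <- new.env(parent = emptyenv())
  m$width <- as.integer(width); m$height <- as.integer(height)
  m$K <- K
  m$alpha <- learning_rate
  m$background_threshold <- background_threshold
  m$var_threshold <- var_threshold
  m$var_floor <- var_floor
  m$init_var <- init_var
  m$means <- numeric(n * K)
  m$vars <- numeric(n * K)
  m$weights <- numeric(n * K)
  m$ncomp <- integer(n)
  class(m) <- "mog_model"
  m
}

check_frame_dims <- function(model, frame) {
  if (nrow(frame) != model$height || ncol(frame) != model$width)
    stop(sprintf("incompatible frame: %dx%d does not match model %dx%d",
                 ncol(frame), nrow(frame), model$width, model$height))
}

#' Classify a frame against the background model and update it
#'
#' @param model A [mog_model()] (updated in place).
#' @param frame Numeric matrix (height x width), intensities on the model's
#'   scale (0-255 by convention).
#' @return Binary foreground mask as an integer matrix (1 = foreground).
#' @export
mog_update_classify <- function(model, frame) {
  check_frame_dims(model, frame)
  mask <- mog_step_cpp(model$means, model$vars, model$weights, model$ncomp,
                       as.numeric(t(frame)), model$K, model$alpha,
                       model$var_threshold, model$background_threshold,
                       model$var_floor, model$init_var)
  matrix(mask, model$height, model$width, byrow = TRUE)
}

#' Reset the background model from a seed frame
#'
#' Replaces every pixel's mixture with a single mode centered at the seed
#' frame, weight 1. Used after a detected lighting change to shorten the
#' re-stabilization time.
#'
#' @param model A [mog_model()] (modified in place).
#' @param frame Seed frame (height x width matrix).
#' @return The model, invisibly.
#' @export
mog_reset <- function(model, frame) {
  check_frame_dims(model, frame)
  n <- model$width * model$height
  K <- model$K
  model$means[] <- 0; model$vars[] <- 0; model$weights[] <- 0
  idx <- (seq_len(n) - 1L) * K + 1L
  model$means[idx] <- as.numeric(t(frame))
  model$vars[idx] <- model$init_var
  model$weights[idx] <- 1
  model$ncomp[] <- 1L
  invisible(model)
}

#' Per-pixel component weight sums (diagnostic)
#' @param model A [mog_model()].
#' @return Numeric vector of per-pixel weight totals.
#' @export
mog_weight_sums <- function(model) {
  rowSums(matrix(model$weights, ncol = model$K, byrow = TRUE))
}

#' Lighting-change configuration
#'
#' @param lighting_change_area Total-foreground-contour-area threshold
#'   (pixels^2) above which a global lighting change is assumed.
#' @param lighting_change_est_time Cooldown (frames) during which no new
#'   lighting change is declared after a reset.
#' @return An object of class `lighting_config`.
#' @export
lighting_config <- function(lighting_change_area, lighting_change_est_time = 30L) {
  stopifnot(lighting_change_area > 0, lighting_change_est_time > 0)
  structure(list(lighting_change_area = lighting_change_area,
                 lighting_change_est_time = as.integer(lighting_change_est_time)),
            class = "lighting_config")
}

#' Decide whether the current frame is a lighting change
#'
#' True iff the total contour area exceeds the threshold and the cooldown
#' since the last declared change has elapsed.
#'
#' @param contours List of contours (as from [extract_contours()]), or a
#'   single total-area number.
#' @param cfg A [lighting_config()].
#' @param frames_since_last_change Frames elapsed since the last declared
#'   lighting change (use `Inf` if none yet).
#' @return Logical flag.
#' @export
check_lighting_change <- function(contours, cfg, frames_since_last_change = Inf) {
  total <- if (is.numeric(contours)) sum(contours)
           else sum(vapply(contours, function(ct) ct$area, numeric(1)))
  total > cfg$lighting_change_area &&
    frames_since_last_change >= cfg$lighting_change_est_time
}

#' Extract 8-connected foreground contours from a binary mask
#'
#' Components below `min_area` are discarded as noise before any area
#' accounting.
#'
#' @param mask Integer/logical matrix (nonzero = foreground).
#' @param min_area Minimum component pixel count.
#' @return List of contours: each a list with `id`, `area` (pixel count) and
#'   `pixels` (N x 2 matrix of 0-based (u, v) coordinates).
#' @export
extract_contours <- function(mask, min_area = 50) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- label8_cpp(m)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(areas >= min_area)
  out <- lapply(seq_along(keep), function(i) {
    rc <- which(lab == keep[i], arr.ind = TRUE)
    list(id = i, area = areas[keep[i]], pixels = rc_to_uv(rc))
  })
  # largest first: candidate ranking downstream is by contour area
  out[order(vapply(out, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Segment one frame with full lighting-change bookkeeping
#'
#' Composes [mog_update_classify()], [extract_contours()],
#' [check_lighting_change()] and, when a change fires, [mog_reset()].
#'
#' @param model A [mog_model()] (updated in place).
#' @param frame Grayscale frame matrix.
#' @param cfg A [lighting_config()].
#' @param frames_since_last_change Frames since the previous declared change.
#' @param min_area Minimum contour area (px) retained.
#' @param close_radius Radius of a morphological closing applied to the raw
#'   mask before contour extraction (0 disables); bridges 1-2 px gaps in the
#'   segmented plant contour.
#' @return List with `mask`, `contours`, `lighting_change`, `model_reset`.
#' @export
segment_frame <- function(model, frame, cfg, frames_since_last_change = Inf,
                          min_area = 50, close_radius = 1L) {
  mask <- mog_update_classify(model, frame)
  if (close_radius > 0) mask <- morph_close(mask, close_radius)
  contours <- extract_contours(mask, min_area)
  change <- check_lighting_change(contours, cfg, frames_since_last_change)
  if (change) {
    mog_reset(model, frame)
    mask[] <- 0L
    contours <- list()
  }
  list(mask = mask, contours = contours,
       lighting_change = change, model_reset = change)
}
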