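# Temporal tip selection, gap interpolation, manual corrections and
# photoperiod-based stereo synchronization.
#
# A track is a data frame with one row per frame in the processed range:
# columns frame_id, u, v, label. Labels follow the detection-type accounting:
#   automatic    - a single candidate existed and was taken
#   estimated    - several candidates; the one nearest the previous tip won
#   interpolated - no candidate; filled linearly from neighboring frames
#   manual       - user-supplied correction
# Unfilled frames carry NA coordinates and label until interpolation.

TIP_LABELS <- c("automatic", "estimated", "interpolated", "manual")

#' Select the tip among a frame's candidates
#'
#' A single candidate is taken as-is (label `automatic`). With several, the
#' Euclidean-nearest to the previously selected tip wins (label
#' `estimated`); without a previous tip the highest-ranked candidate wins.
#' Distance ties break toward the lower candidate index. No candidates
#' yield `NULL`.
#'
#' @param candidates A `candidate_set` data frame (ranked by contour area).
#' @param previous Length-2 pixel of the last selected tip, or `NULL`.
#' @return List with `pixel` (c(u, v)) and `label`, or `NULL`.
#' @export
select_tip <- function(candidates, previous = NULL) {
  n <- nrow(candidates)
  if (n == 0) return(NULL)
  if (n == 1)
    return(list(pixel = c(u = candidates$u[1], v = candidates$v[1]),
                label = "automatic"))
  i <- if (is.null(previous)) 1L else {
    d <- (candidates$u - previous[1])^2 + (candidates$v - previous[2])^2
    which.min(d)  # first minimum = lowest index on ties
  }
  list(pixel = c(u = candidates$u[i], v = candidates$v[i]), label = "estimated")
}

new_track <- function(frame_ids) {
  data.frame(frame_id = frame_ids, u = NA_real_, v = NA_real_,
             label = NA_character_, stringsAsFactors = FALSE)
}

#' Fill track gaps by linear interpolation
#'
#' Interior gaps are filled per-coordinate between the bounding
#' observations; leading/trailing gaps hold the nearest observation. Filled
#' frames are labeled `interpolated`.
#'
#' @param track Track data frame (frame_id, u, v, label), NA rows = gaps.
#' @return Gap-free track.
#' @export
interpolate_gaps <- function(track) {
  obs <- which(!is.na(track$u))
  if (!length(obs)) stop("nothing to interpolate: track has no observations")
  gaps <- which(is.na(track$u))
  if (length(gaps)) {
    if (length(obs) == 1) {
      track$u[gaps] <- track$u[obs]
      track$v[gaps] <- track$v[obs]
    } else {
      f <- track$frame_id
      track$u[gaps] <- stats::approx(f[obs], track$u[obs], xout = f[gaps],
                                     rule = 2)$y
      track$v[gaps] <- stats::approx(f[obs], track$v[obs], xout = f[gaps],
                                     rule = 2)$y
    }
    track$label[gaps] <- "interpolated"
  }
  track
}

#' Apply manual corrections to a track
#'
#' Corrected frames take the supplied pixel and the label `manual` (even
#' when the value is unchanged, so the detection-type accounting reflects
#' operator effort). All interpolated frames are then recomputed, so gaps
#' bounded by a corrected observation stay consistent.
#'
#' @param track Gap-free or gappy track data frame.
#' @param corrections Data frame with columns frame_id, u, v (any extra
#'   columns, e.g. view, are ignored here).
#' @return Corrected track.
#' @export
apply_corrections <- function(track, corrections) {
  if (is.null(corrections) || nrow(corrections) == 0) return(track)
  bad <- setdiff(corrections$frame_id, track$frame_id)
  if (length(bad))
    stop(sprintf("invalid correction: frame %s outside the processed range", bad[1]))
  i <- match(corrections$frame_id, track$frame_id)
  track$u[i] <- corrections$u
  track$v[i] <- corrections$v
  track$label[i] <- "manual"
  redo <- !is.na(track$label) & track$label == "interpolated"
  if (any(redo)) {
    track$u[redo] <- NA_real_; track$v[redo] <- NA_real_
    track$label[redo] <- NA_character_
    track <- interpolate_gaps(track)
  }
  track
}

#' Photoperiod synchronization result
#' @param offset_frames Signed frame offset (side relative to top).
#' @param transitions_top,transitions_side Frame indices of light/dark steps.
#' @return An object of class `sync_result`.
#' @export
sync_result <- function(offset_frames, transitions_top, transitions_side) {
  structure(list(offset_frames = as.integer(offset_frames),
                 transitions_top = transitions_top,
                 transitions_side = transitions_side),
            class = "sync_result")
}

find_light_transitions <- function(lum) {
  dr <- diff(range(lum))
  if (dr <= 0) return(integer(0))
  which(abs(diff(lum)) > dr / 2)
}

#' Estimate the inter-camera frame offset from the photoperiod signal
#'
#' Light/dark steps are located in each camera's mean-luminance series as
#' first differences exceeding half the series' dynamic range; the offset is
#' the index difference of the first matched transitions (side minus top).
#'
#' @param luminance_top,luminance_side Per-frame mean intensity series.
#' @return A [sync_result()].
#' @export
estimate_offset <- function(luminance_top, luminance_side) {
  tt <- find_light_transitions(luminance_top)
  ts <- find_light_transitions(luminance_side)
  if (!length(tt) || !length(ts))
    stop("unsynchronizable: no photoperiod transition found in a series")
  # candidate offsets from every transition pairing; keep the one aligning
  # the most transitions (ties: smallest |offset|), since either sequence
  # may open mid-phase with unmatched boundary transitions
  cand <- sort(unique(as.numeric(outer(ts, tt, "-"))))
  score <- vapply(cand, function(o) sum((tt + o) %in% ts), numeric(1))
  best <- cand[score == max(score)]
  off <- best[which.min(abs(best))]
  if (abs(off) >= min(length(luminance_top), length(luminance_side)))
    stop("unsynchronizable: offset exceeds sequence length")
  sync_result(off, tt, ts)
}

#' Detection-type counts per view
#'
#' @param track_top,track_side Gap-free track data frames.
#' @return Data frame with one row per view and columns automatic, manual,
#'   estimated, interpolated, total.
#' @export
detection_summary <- function(track_top, track_side) {
  count1 <- function(track, view) {
    if (any(is.na(track$label))) stop("detection_summary needs gap-free tracks")
    n <- vapply(c("automatic", "manual", "estimated", "interpolated"),
                function(l) sum(track$label == l), numeric(1))
    data.frame(view = view, automatic = n[1], manual = n[2], estimated = n[3],
               interpolated = n[4], total = nrow(track))
  }
  rbind(count1(track_top, "top"), count1(track_side, "side"))
}

# ---- CSV interfaces ---------------------------------------------------------

#' Write a per-view track to CSV (frame_id, view, u, v, label)
#' @param track Track data frame.
#' @param view View tag added to each row.
#' @param path Output path.
#' @export
write_track_csv <- function(track, view, path) {
  out <- data.frame(frame_id = track$frame_id, view = view,
                    u = track$u, v = track$v, label = track$label)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a track CSV written by [write_track_csv()]
#' @param path CSV path.
#' @param view Optional view filter.
#' @return Track data frame.
#' @export
read_track_csv <- function(path, view = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(view)) x <- x[x$view == view, ]
  data.frame(frame_id = x$frame_id, u = x$u, v = x$v, label = x$label,
             stringsAsFactors = FALSE)
}

#' Read a manual-corrections CSV (header frame_id, view, u, v)
#' @param path CSV path.
#' @return Data frame of corrections.
#' @export
read_corrections_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "view", "u", "v")
  if (!all(need %in% names(x)))
    stop("corrections CSV must have header columns frame_id, view, u, v")
  x[need]
}
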