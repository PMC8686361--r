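# ---- pelvis frame helpers (shared with the feature module) ----

# n x 2 horizontal left-ASIS -> right-ASIS vector
pelvis_ml_vec <- function(set) {
  v <- set$markers[["RASI"]][, 1:2] - set$markers[["LASI"]][, 1:2]
  v
}

# horizontal unit vectors of the pelvis frame: ml (left->right) and anterior
pelvis_axes <- function(set) {
  v <- pelvis_ml_vec(set)
  len <- sqrt(rowSums(v^2))
  if (any(!is.finite(len)) || any(len < 1e-9))
    stop("degenerate or missing ASIS markers: pelvic vector undefined")
  ml <- v / len
  ant <- cbind(-ml[, 2], ml[, 1])  # +90 deg rotation: left->right to anterior
  list(ml = ml, anterior = ant)
}

pelvis_center <- function(set) {
  (set$markers[["LASI"]] + set$markers[["RASI"]] +
     set$markers[["LPSI"]] + set$markers[["RPSI"]]) / 4
}

unwrap_rad <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

#' Cumulative pelvic heading during a trial
#'
#' The per-frame angle between the horizontal projection of the left-to-right
#' ASIS (pelvic) vector and the global X axis, unwrapped cumulatively and
#' referenced to the first frame, in degrees. During a turn it grows
#' monotonically (up to noise) to +/- 360.
#'
#' @param set A [marker_set()] containing LASI and RASI.
#' @return Numeric vector of length `n_frames` (degrees, heading of frame 1
#'   is 0).
#' @export
compute_pelvic_heading <- function(set) {
  v <- pelvis_ml_vec(set)
  if (any(!is.finite(v)))
    stop("missing ASIS samples inside the trial; fill gaps first")
  theta <- atan2(v[, 2], v[, 1])
  h <- unwrap_rad(theta)
  (h - h[1]) * 180 / pi
}

#' Detect the 360-degree turn analysis window
#'
#' The analysis window starts when the cumulative pelvic heading passes 10
#' degrees and ends when it completes 360 degrees, so 350 degrees of
#' rotation are analysed. Crossings are refined to sub-frame precision by
#' linear interpolation (used for durations); frame indices are the first
#' frames at or beyond each threshold.
#'
#' @param heading Heading sequence from [compute_pelvic_heading()] (degrees).
#' @param rate Sampling rate (Hz).
#' @param start_deg,end_deg Window thresholds on cumulative rotation.
#' @return List with `start_frame`, `end_frame`, `start_time`, `end_time`,
#'   `duration` (s, sub-frame refined) and `direction` (+1 counter-clockwise,
#'   -1 clockwise).
#' @export
detect_turn_phase <- function(heading, rate, start_deg = 10, end_deg = 360) {
  h <- abs(heading)
  direction <- sign(heading[which.max(h)])
  if (max(h) < end_deg)
    stop(sprintf("incomplete turn: heading reaches only %.1f of %g degrees",
                 max(h), end_deg))
  cross_time <- function(thr) {
    i <- which(h >= thr)[1]
    if (i == 1L) return(list(frame = 1L, time = 0))
    frac <- (thr - h[i - 1L]) / (h[i] - h[i - 1L])
    list(frame = i, time = (i - 2L + frac) / rate)
  }
  s <- cross_time(start_deg)
  e <- cross_time(end_deg)
  list(start_frame = s$frame, end_frame = e$frame,
       start_time = s$time, end_time = e$time,
       duration = e$time - s$time, direction = direction)
}

# rising/falling edges of a contact mask, separated by >= min_sep frames
edge_events <- function(mask, min_sep) {
  d <- diff(c(FALSE, mask))
  rise <- which(d == 1L)
  rise <- rise[rise > 1L]  # contact from the first frame is not a strike
  fall <- which(d == -1L) - 1L  # last frame still in contact
  thin <- function(idx) {
    if (length(idx) < 2L) return(idx)
    keep <- idx[1]
    for (i in idx[-1]) if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
    keep
  }
  list(rise = thin(rise), fall = thin(fall))
}

#' Detect heel strikes and toe offs inside the turn window
#'
#' Coordinate-based detector (no force plates): a foot is in ground contact
#' while its marker sits on its vertical-minimum plateau with near-zero
#' vertical velocity. Heel strike is the onset of heel-marker contact (the
#' heel descending onto its local minimum); toe off is the offset of
#' toe-marker contact (the toe vertical velocity turning positive as the
#' foot leaves its plateau). The contact plateau is found by an adaptive
#' height threshold above the per-marker minimum; successive same-type
#' events closer than `min_step_time` are merged. The detector is
#' deliberately simple and swappable.
#'
#' @param set A filtered [marker_set()] with HEE and TOE markers.
#' @param window Turn window from [detect_turn_phase()]; `NULL` uses the
#'   whole trial.
#' @param min_step_time Minimum time between successive events of the same
#'   type on one foot (s).
#' @param height_frac Fraction of the marker's vertical excursion used for
#'   the contact threshold.
#' @param min_height Lower bound on the contact threshold (m).
#' @return A list with per-foot (`left`, `right`) components, each holding
#'   integer vectors `heel_strikes` and `toe_offs` (frame indices, clipped to
#'   the window), plus `window`.
#' @export
detect_gait_events <- function(set, window = NULL, min_step_time = 0.3,
                               height_frac = 0.08, min_height = 0.004) {
  frames <- if (is.null(window)) c(1L, set$n_frames) else
    c(window$start_frame, window$end_frame)
  min_sep <- max(1L, round(min_step_time * set$rate))
  per_foot <- function(prefix) {
    heel_z <- set$markers[[paste0(prefix, "HEE")]][, 3]
    toe_z <- set$markers[[paste0(prefix, "TOE")]][, 3]
    contact <- function(z) {
      thr <- min(z) + max(min_height, height_frac * (max(z) - min(z)))
      z <= thr
    }
    hs <- edge_events(contact(heel_z), min_sep)$rise
    to <- edge_events(contact(toe_z), min_sep)$fall
    hs <- hs[hs >= frames[1] & hs <= frames[2]]
    to <- to[to >= frames[1] & to <= frames[2]]
    list(heel_strikes = hs, toe_offs = to)
  }
  ev <- list(left = per_foot("L"), right = per_foot("R"))
  n_ev <- sum(lengths(ev$left)) + sum(lengths(ev$right))
  if (n_ev == 0L)
    stop("no steps in window: no gait events detected")
  c(ev, list(window = frames))
}

#' Count steps and measure turn duration
#'
#' Steps are heel strikes inside the analysis window summed over both feet;
#' the duration comes from the sub-frame-refined 10/360 degree crossings.
#'
#' @param events Event structure from [detect_gait_events()].
#' @param window Turn window from [detect_turn_phase()].
#' @return List with `steps` (integer) and `duration` (s).
#' @export
count_steps <- function(events, window) {
  steps <- length(events$left$heel_strikes) + length(events$right$heel_strikes)
  list(steps = steps, duration = window$duration)
}

# contact indicator over [from, to] reconstructed from alternating events;
# assumes contact from window start when the first event is a toe off
contact_indicator <- function(foot_events, from, to) {
  ind <- logical(to - from + 1L)
  hs <- foot_events$heel_strikes
  tos <- foot_events$toe_offs
  ev <- rbind(
    if (length(hs)) data.frame(frame = hs, type = "hs"),
    if (length(tos)) data.frame(frame = tos, type = "to")
  )
  if (is.null(ev) || nrow(ev) == 0L) return(ind)
  ev <- ev[order(ev$frame), ]
  state <- ev$type[1] == "to"  # in contact before a leading toe off
  cur <- from
  for (i in seq_len(nrow(ev))) {
    f <- min(max(ev$frame[i], from), to + 1L)
    if (f > cur) ind[(cur - from + 1L):(f - from)] <- state
    state <- ev$type[i] == "hs"
    cur <- max(cur, f)
  }
  if (cur <= to) ind[(cur - from + 1L):(to - from + 1L)] <- state
  ind
}
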