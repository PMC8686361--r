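#' Canonical turning-feature registry
#'
#' Names of the turning features computed by [extract_features()]:
#' spatiotemporal measures, sagittal ranges of motion, toe clearances,
#' trunk-pelvis dissociation (maximum anti-phase), whole-body incline,
#' arm-leg temporal coordination parameters (ipsilateral and contralateral,
#' inner and outer arm) and horizontal centre-of-mass path statistics.
#' Lengths are reported in cm, angles in degrees, times in seconds, the COM
#' ellipse area in cm^2, COM path distance in m and COM velocity in m/s.
#' The registry is extensible: `extra` appends additional named slots which
#' are carried through averaging as `NA` unless a custom extractor fills
#' them.
#'
#' @param extra Character vector of additional feature names.
#' @return Character vector of feature names.
#' @export
feature_registry <- function(extra = character()) {
  c("steps_total", "turn_duration", "step_width",
    "step_length_inner", "step_length_outer",
    "single_support_inner", "single_support_outer",
    "double_support_inner", "double_support_outer",
    "stance_inner", "stance_outer",
    "rom_hip_inner", "rom_hip_outer", "rom_knee_inner", "rom_knee_outer",
    "rom_ankle_inner", "rom_ankle_outer",
    "rom_shoulder_inner", "rom_shoulder_outer",
    "rom_pelvis", "rom_thorax",
    "toe_clearance_inner", "toe_clearance_outer",
    "max_anti_phase", "incline_angle",
    "dt_ipsi_inner", "dt_ipsi_outer", "dt_contra_inner", "dt_contra_outer",
    "com_area_95ci", "com_rms_ap", "com_rms_ml",
    "com_total_distance", "com_velocity",
    extra)
}

#' Segment a turning trial
#'
#' Convenience wrapper combining [compute_pelvic_heading()],
#' [detect_turn_phase()] and [detect_gait_events()] into the segmentation
#' object consumed by the feature extractors.
#'
#' @param set A filtered [marker_set()].
#' @param inner_side `"left"` or `"right"`: the limb performing the inner
#'   steps.
#' @param ... Passed to [detect_gait_events()].
#' @return List with `heading`, `window`, `events`, `inner_foot`,
#'   `outer_foot`.
#' @export
segment_turn <- function(set, inner_side, ...) {
  inner_side <- match.arg(inner_side, c("left", "right"))
  heading <- compute_pelvic_heading(set)
  window <- detect_turn_phase(heading, set$rate)
  events <- detect_gait_events(set, window, ...)
  list(heading = heading, window = window, events = events,
       inner_foot = inner_side,
       outer_foot = setdiff(c("left", "right"), inner_side))
}

foot_prefix <- function(side) if (side == "left") "L" else "R"

# ---- angle helpers ----

unwrap_deg <- function(a) {
  d <- diff(a)
  d <- d - 360 * round(d / 360)
  cumsum(c(a[1], d))
}

# sagittal-plane angle series (deg) of a segment-vector matrix W (n x 3),
# measured in the plane normal to the pelvis ML axis: 0 = straight down,
# positive tilting toward the pelvis anterior direction
sagittal_angle <- function(W, axes) {
  len <- sqrt(rowSums(W^2))
  if (any(!is.finite(len)) || any(len < 1e-9))
    stop("degenerate (zero-length) segment vector")
  comp_a <- W[, 1] * axes$anterior[, 1] + W[, 2] * axes$anterior[, 2]
  comp_z <- W[, 3]
  unwrap_deg(atan2(comp_a, -comp_z) * 180 / pi)
}

window_frames <- function(seg) seg$window$start_frame:seg$window$end_frame

# ---- spatiotemporal ----

#' Spatiotemporal turning features
#'
#' Step width and inner/outer step lengths are measured at heel strikes:
#' for each successive pair of contralateral contacts the displacement from
#' the earlier to the later heel position is decomposed along the pelvis
#' anterior direction at the later contact (step length, assigned to the
#' stepping foot) and perpendicular to it (step width). Single support,
#' double support and stance are expressed as a percentage of the stepping
#' foot's gait cycle (heel strike to next ipsilateral heel strike) and
#' averaged over cycles.
#'
#' @param set A filtered [marker_set()].
#' @param seg Segmentation from [segment_turn()].
#' @return Named list of features (lengths in cm, phases in % of cycle);
#'   entries are `NA` when fewer than two contacts make them non-computable.
#' @export
spatiotemporal_features <- function(set, seg) {
  axes <- pelvis_axes(set)
  contacts <- do.call(rbind, lapply(c("left", "right"), function(side) {
    hs <- seg$events[[side]]$heel_strikes
    if (length(hs) == 0L) return(NULL)
    p <- set$markers[[paste0(foot_prefix(side), "HEE")]][hs, 1:2, drop = FALSE]
    data.frame(frame = hs, foot = side, x = p[, 1], y = p[, 2])
  }))
  out <- list(step_width = NA_real_, step_length_inner = NA_real_,
              step_length_outer = NA_real_)
  if (!is.null(contacts) && nrow(contacts) >= 2L) {
    contacts <- contacts[order(contacts$frame), ]
    widths <- c(); sl <- list(inner = c(), outer = c())
    for (i in 2:nrow(contacts)) {
      if (contacts$foot[i] == contacts$foot[i - 1]) next
      d <- c(contacts$x[i] - contacts$x[i - 1],
             contacts$y[i] - contacts$y[i - 1])
      u <- axes$anterior[contacts$frame[i], ]
      nl <- axes$ml[contacts$frame[i], ]
      widths <- c(widths, abs(sum(d * nl)))
      role <- if (contacts$foot[i] == seg$inner_foot) "inner" else "outer"
      sl[[role]] <- c(sl[[role]], abs(sum(d * u)))
    }
    if (length(widths)) out$step_width <- 100 * mean(widths)
    if (length(sl$inner)) out$step_length_inner <- 100 * mean(sl$inner)
    if (length(sl$outer)) out$step_length_outer <- 100 * mean(sl$outer)
  }

  from <- seg$window$start_frame; to <- seg$window$end_frame
  ind <- list(left = contact_indicator(seg$events$left, from, to),
              right = contact_indicator(seg$events$right, from, to))
  for (role in c("inner", "outer")) {
    side <- if (role == "inner") seg$inner_foot else seg$outer_foot
    other <- setdiff(c("left", "right"), side)
    hs <- seg$events[[side]]$heel_strikes
    tos <- seg$events[[side]]$toe_offs
    ss <- ds <- st <- c()
    if (length(hs) >= 2L) {
      for (i in seq_len(length(hs) - 1L)) {
        cyc <- hs[i]:(hs[i + 1L] - 1L)
        cyc <- cyc[cyc >= from & cyc <= to]
        if (length(cyc) < 2L) next
        me <- ind[[side]][cyc - from + 1L]
        ot <- ind[[other]][cyc - from + 1L]
        ds <- c(ds, 100 * mean(me & ot))
        ss <- c(ss, 100 * mean(me & !ot))
        to_i <- tos[tos > hs[i] & tos < hs[i + 1L]]
        if (length(to_i) == 1L)
          st <- c(st, 100 * (to_i - hs[i]) / (hs[i + 1L] - hs[i]))
      }
    }
    out[[paste0("single_support_", role)]] <-
      if (length(ss)) mean(ss) else NA_real_
    out[[paste0("double_support_", role)]] <-
      if (length(ds)) mean(ds) else NA_real_
    out[[paste0("stance_", role)]] <- if (length(st)) mean(st) else NA_real_
  }
  out
}

# ---- sagittal ROM ----

#' Sagittal range-of-motion features
#'
#' Joint angles are computed from marker-level segment vectors projected
#' onto the plane normal to the pelvis mediolateral axis (no full 3-D Euler
#' decomposition): hip = thigh (ASIS to lateral knee marker) relative to the
#' pelvis longitudinal axis; knee = thigh relative to shank (knee to ankle
#' marker); ankle = shank relative to foot (heel to toe); shoulder =
#' upper arm (shoulder to lateral elbow marker) relative to the thorax
#' longitudinal axis (C7-T10); pelvis and thorax pitch are measured against
#' the global vertical. ROM = max - min over the analysis window, degrees.
#'
#' @inheritParams spatiotemporal_features
#' @return Named list of ROM values (degrees).
#' @export
joint_rom_features <- function(set, seg) {
  axes <- pelvis_axes(set)
  wf <- window_frames(seg)
  m <- set$markers
  # pelvis longitudinal (down) axis = anterior x ml (3-D)
  a3 <- (m[["LASI"]] + m[["RASI"]]) / 2 - (m[["LPSI"]] + m[["RPSI"]]) / 2
  a3 <- a3 / sqrt(rowSums(a3^2))
  m3 <- cbind(axes$ml, 0)
  pelvis_down <- cbind(
    a3[, 2] * m3[, 3] - a3[, 3] * m3[, 2],
    a3[, 3] * m3[, 1] - a3[, 1] * m3[, 3],
    a3[, 1] * m3[, 2] - a3[, 2] * m3[, 1])
  thorax_down <- m[["T10"]] - m[["C7"]]

  ang <- function(W) sagittal_angle(W, axes)
  rom <- function(series) diff(range(series[wf]))
  th_pelvis <- ang(pelvis_down)
  th_thorax <- ang(thorax_down)
  out <- list()
  for (role in c("inner", "outer")) {
    side <- if (role == "inner") seg$inner_foot else seg$outer_foot
    p <- foot_prefix(side)
    thigh <- m[[paste0(p, "KNE")]] - m[[paste0(p, "ASI")]]
    shank <- m[[paste0(p, "ANK")]] - m[[paste0(p, "KNE")]]
    foot <- m[[paste0(p, "TOE")]] - m[[paste0(p, "HEE")]]
    uarm <- m[[paste0(p, "ELB")]] - m[[paste0(p, "SHO")]]
    th_thigh <- ang(thigh); th_shank <- ang(shank)
    out[[paste0("rom_hip_", role)]] <- rom(th_thigh - th_pelvis)
    out[[paste0("rom_knee_", role)]] <- rom(th_thigh - th_shank)
    out[[paste0("rom_ankle_", role)]] <- rom(th_shank - ang(foot))
    out[[paste0("rom_shoulder_", role)]] <- rom(ang(uarm) - th_thorax)
  }
  out$rom_pelvis <- rom(th_pelvis)
  out$rom_thorax <- rom(th_thorax)
  out
}

# ---- toe clearance ----

#' Toe clearance during swing
#'
#' Per step: the maximum vertical toe-marker height during the swing phase
#' (toe off to the next ipsilateral heel strike) minus the foot's stance
#' baseline (median toe height over ground-contact frames); averaged over
#' steps per foot, reported in cm.
#'
#' @inheritParams spatiotemporal_features
#' @return List with `toe_clearance_inner` and `toe_clearance_outer` (cm);
#'   `NA` when a foot has no complete swing phase in the window.
#' @export
toe_clearance <- function(set, seg) {
  from <- seg$window$start_frame; to <- seg$window$end_frame
  out <- list()
  for (role in c("inner", "outer")) {
    side <- if (role == "inner") seg$inner_foot else seg$outer_foot
    z <- set$markers[[paste0(foot_prefix(side), "TOE")]][, 3]
    ev <- seg$events[[side]]
    ind <- contact_indicator(ev, from, to)
    baseline <- stats::median(z[from:to][ind])
    vals <- c()
    for (tf in ev$toe_offs) {
      nh <- ev$heel_strikes[ev$heel_strikes > tf]
      if (length(nh) == 0L) next
      swing <- (tf + 1L):min(nh[1], to)
      if (length(swing) < 2L) next
      vals <- c(vals, max(z[swing]) - baseline)
    }
    out[[paste0("toe_clearance_", role)]] <-
      if (length(vals)) 100 * mean(vals) else NA_real_
  }
  out
}

# ---- trunk rotation dissociation & lean ----

#' Maximum anti-phase between shoulder and pelvic vectors
#'
#' Per-frame horizontal-plane angle between the inner-to-outer ASIS vector
#' and the inner-to-outer shoulder-marker vector; the maximum over the
#' analysis window quantifies trunk-on-pelvis rotational dissociation
#' (degrees).
#'
#' @inheritParams spatiotemporal_features
#' @return Maximum anti-phase angle in degrees.
#' @export
max_anti_phase <- function(set, seg) {
  ip <- foot_prefix(seg$inner_foot); op <- foot_prefix(seg$outer_foot)
  wf <- window_frames(seg)
  pv <- (set$markers[[paste0(op, "ASI")]] -
           set$markers[[paste0(ip, "ASI")]])[wf, 1:2, drop = FALSE]
  sv <- (set$markers[[paste0(op, "SHO")]] -
           set$markers[[paste0(ip, "SHO")]])[wf, 1:2, drop = FALSE]
  np <- sqrt(rowSums(pv^2)); ns <- sqrt(rowSums(sv^2))
  if (any(np < 1e-9) || any(ns < 1e-9))
    stop("degenerate pelvic or shoulder vector")
  cosang <- pmin(1, pmax(-1, rowSums(pv * sv) / (np * ns)))
  max(acos(cosang)) * 180 / pi
}

#' Whole-body incline angle
#'
#' Per-frame angle between the vector from the base-of-support reference
#' point to the head-segment centre (centroid of the four head markers) and
#' the global vertical; the maximum over the window measures lean toward
#' the cone. The base-of-support point is the midpoint of the two feet's
#' heel-toe midpoints, a smooth marker-defined proxy that avoids
#' discontinuities at support transitions.
#'
#' @inheritParams spatiotemporal_features
#' @return Maximum incline angle in degrees.
#' @export
incline_angle <- function(set, seg) {
  wf <- window_frames(seg)
  m <- set$markers
  head <- (m[["LFHD"]] + m[["RFHD"]] + m[["LBHD"]] + m[["RBHD"]]) / 4
  if (any(!is.finite(head[wf, ]))) stop("degenerate head centroid")
  feet <- (m[["LHEE"]] + m[["LTOE"]] + m[["RHEE"]] + m[["RTOE"]]) / 4
  v <- (head - feet)[wf, , drop = FALSE]
  if (any(v[, 3] <= 0)) stop("head centroid below base of support")
  max(atan2(sqrt(v[, 1]^2 + v[, 2]^2), v[, 3])) * 180 / pi
}

# ---- temporal coordination ----

find_peaks <- function(x, min_sep) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) < 2L) return(cand)
  cand <- cand[order(-x[cand])]
  keep <- integer()
  for (i in cand) if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  sort(keep)
}

#' Arm-leg temporal coordination parameters
#'
#' For each limb the anterior-posterior displacement of its distal marker
#' (lateral humeral epicondyle for the arm, lateral femoral epicondyle for
#' the leg) is expressed in the pelvis-fixed frame (global AP is
#' meaningless during turning). Per gait cycle, the absolute time
#' difference between an arm peak and its nearest leg peak is averaged:
#' inner arm-inner leg (ipsilateral inner), outer arm-outer leg
#' (ipsilateral outer), inner arm-outer leg (contralateral inner) and outer
#' arm-inner leg (contralateral outer). Unmatched peaks at the window edges
#' are dropped.
#'
#' @inheritParams spatiotemporal_features
#' @return List with `dt_ipsi_inner`, `dt_ipsi_outer`, `dt_contra_inner`,
#'   `dt_contra_outer` (seconds; `NA` when no peaks are detectable).
#' @export
temporal_coordination <- function(set, seg) {
  axes <- pelvis_axes(set)
  pc <- pelvis_center(set)[, 1:2]
  wf <- window_frames(seg)
  ap_series <- function(label) {
    r <- set$markers[[label]][, 1:2] - pc
    (r[, 1] * axes$anterior[, 1] + r[, 2] * axes$anterior[, 2])[wf]
  }
  n_steps <- length(seg$events$left$heel_strikes) +
    length(seg$events$right$heel_strikes)
  stride_frames <- if (n_steps >= 2L)
    2 * length(wf) / n_steps else length(wf) / 2
  min_sep <- max(3L, round(0.6 * stride_frames))
  peaks_of <- function(label) {
    p <- find_peaks(ap_series(label), min_sep)
    (wf[1] - 1L + p - 1L)[seq_along(p)] / set$rate
  }
  sides <- list(inner = foot_prefix(seg$inner_foot),
                outer = foot_prefix(seg$outer_foot))
  arm <- lapply(sides, function(p) peaks_of(paste0(p, "ELB")))
  leg <- lapply(sides, function(p) peaks_of(paste0(p, "KNE")))
  half_stride <- stride_frames / (2 * set$rate)
  pair_dt <- function(ta, tl) {
    if (length(ta) == 0L || length(tl) == 0L) return(NA_real_)
    d <- vapply(ta, function(t) min(abs(t - tl)), numeric(1))
    d <- d[d <= half_stride]  # drop unmatched edge peaks
    if (length(d) == 0L) NA_real_ else mean(d)
  }
  list(dt_ipsi_inner = pair_dt(arm$inner, leg$inner),
       dt_ipsi_outer = pair_dt(arm$outer, leg$outer),
       dt_contra_inner = pair_dt(arm$inner, leg$outer),
       dt_contra_outer = pair_dt(arm$outer, leg$inner))
}

# ---- centre of mass ----

#' Estimate the horizontal centre-of-mass trajectory
#'
#' Two marker-level estimates are available. `"pelvis"` (default) uses the
#' centroid of the four pelvis markers, a standard proxy for whole-body COM
#' in gait. `"segments"` uses a weighted centroid of pelvis, thorax and
#' head marker groups with trunk-dominant anthropometric mass fractions
#' (pelvis+legs 0.50, thorax+arms 0.42, head 0.08 of body mass lumped at
#' the respective marker centroids). The provenance is recorded in the
#' result.
#'
#' @param set A filtered [marker_set()].
#' @param method `"pelvis"` or `"segments"`.
#' @return List of class `com_trajectory` with `xy` (n x 2, metres),
#'   `xyz` and `method`.
#' @export
com_trajectory <- function(set, method = c("pelvis", "segments")) {
  method <- match.arg(method)
  m <- set$markers
  pel <- pelvis_center(set)
  if (method == "pelvis") {
    xyz <- pel
  } else {
    thx <- (m[["C7"]] + m[["T10"]] + m[["CLAV"]] + m[["STRN"]]) / 4
    head <- (m[["LFHD"]] + m[["RFHD"]] + m[["LBHD"]] + m[["RBHD"]]) / 4
    xyz <- 0.50 * pel + 0.42 * thx + 0.08 * head
  }
  structure(list(xy = xyz[, 1:2, drop = FALSE], xyz = xyz, method = method),
            class = "com_trajectory")
}

#' Horizontal centre-of-mass path features
#'
#' Over the analysis window: the area of the 95% prediction ellipse of the
#' horizontal COM positions (`pi * chi^2_{0.95,2} * sqrt(det(Sigma))`, cm^2),
#' RMS deviations from the window mean along the global anterior-posterior
#' (Y) and mediolateral (X) axes (cm), the COM path length (m) and the mean
#' COM velocity (path length / window duration, m/s).
#'
#' @param com A [com_trajectory()].
#' @param seg Segmentation from [segment_turn()].
#' @param rate Sampling rate (Hz).
#' @return Named list with `com_area_95ci`, `com_rms_ap`, `com_rms_ml`,
#'   `com_total_distance`, `com_velocity`.
#' @export
com_features <- function(com, seg, rate) {
  wf <- window_frames(seg)
  if (length(wf) < 3L) stop("need at least 3 frames of COM data")
  xy <- com$xy[wf, , drop = FALSE]
  S <- stats::cov(xy)
  area_m2 <- pi * stats::qchisq(0.95, df = 2) * sqrt(max(det(S), 0))
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  dist <- sum(sqrt(dx^2 + dy^2))
  dur <- seg$window$duration
  list(com_area_95ci = 1e4 * area_m2,
       com_rms_ml = 100 * sqrt(mean((xy[, 1] - mean(xy[, 1]))^2)),
       com_rms_ap = 100 * sqrt(mean((xy[, 2] - mean(xy[, 2]))^2)),
       com_total_distance = dist,
       com_velocity = dist / dur)
}

# ---- full extraction ----

#' Extract the full turning-feature vector from one or more trials
#'
#' Runs the whole chain on each trial: gap interpolation, zero-phase
#' low-pass filtering, pelvic-heading turn segmentation, gait-event
#' detection and all feature groups. When several trials of the same
#' subject are supplied the per-trial vectors are averaged element-wise
#' (the convention for repeated turning trials). Non-computable entries are
#' `NA` and listed in the `flags` attribute.
#'
#' @param sets A [marker_set()] or list of marker sets (trials of one
#'   subject).
#' @param metadata A [trial_metadata()] (only `inner_side` is used here).
#' @param filter A [filter_spec()]; `NULL` skips filtering.
#' @param max_gap_frames Passed to [interpolate_gaps()].
#' @param com_method Passed to [com_trajectory()].
#' @param registry Feature name registry; computed features not in the
#'   registry are dropped, registry slots without an extractor stay `NA`.
#' @return Named numeric vector over `registry`, with attribute `flags`
#'   naming non-computable features.
#' @export
extract_features <- function(sets, metadata, filter = filter_spec(),
                             max_gap_frames = 10,
                             com_method = c("pelvis", "segments"),
                             registry = feature_registry()) {
  com_method <- match.arg(com_method)
  if (inherits(sets, "marker_set")) sets <- list(sets)
  one <- function(set) {
    set <- interpolate_gaps(set, max_gap_frames)
    if (!is.null(filter)) set <- filter_lowpass(set, filter)
    seg <- segment_turn(set, metadata$inner_side)
    sc <- count_steps(seg$events, seg$window)
    vals <- c(list(steps_total = sc$steps, turn_duration = sc$duration),
              spatiotemporal_features(set, seg),
              joint_rom_features(set, seg),
              toe_clearance(set, seg),
              list(max_anti_phase = max_anti_phase(set, seg),
                   incline_angle = incline_angle(set, seg)),
              temporal_coordination(set, seg),
              com_features(com_trajectory(set, com_method), seg, set$rate))
    unlist(vals)
  }
  per_trial <- vapply(sets, one, numeric(34L))
  avg <- rowMeans(per_trial, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  out <- stats::setNames(rep(NA_real_, length(registry)), registry)
  common <- intersect(names(avg), registry)
  out[common] <- avg[common]
  attr(out, "flags") <- names(out)[is.na(out)]
  out
}
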