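#' Parameters of the turning puppet
#'
#' The puppet is a purely kinematic full-body marker generator: a body
#' walks a 360-degree circular path about a cone with parameterised step
#' geometry, stance timing, sagittal joint oscillations, trunk-pelvis yaw
#' dissociation, whole-body lean, arm-leg phase lag and marker noise. It is
#' feature-consistent rather than skeleton-consistent: each marker group is
#' constructed so that the corresponding feature definition recovers the
#' programmed value, which is sufficient because every turning feature is
#' geometric or temporal. Defaults describe an unimpaired older adult
#' turning at preferred speed (about 12 steps, 6.7 s for the full turn).
#'
#' Angle amplitudes are half-ranges: a sagittal oscillation of amplitude
#' `A` degrees yields a range of motion of `2 A` degrees. `amp_hip`,
#' `amp_knee`, `amp_ankle`, `amp_shoulder` may be single numbers or
#' length-2 vectors `c(inner, outer)`.
#'
#' @param cadence Steps per second.
#' @param n_steps Steps over the 360-degree turn.
#' @param step_length_inner,step_length_outer Step lengths (m).
#' @param step_width Step width (m).
#' @param stance_fraction Stance fraction of the gait cycle, in (0.5, 0.9).
#' @param amp_hip,amp_knee,amp_shoulder Sagittal amplitudes (deg).
#' @param amp_ankle Swing foot-pitch amplitude (deg); ankle ROM responds
#'   monotonically but is an emergent quantity (see the ground-truth log).
#' @param amp_pelvis,amp_thorax Pelvis / thorax pitch amplitudes (deg).
#' @param yaw_offset_peak Peak trunk-on-pelvis yaw (deg) -> maximum
#'   anti-phase.
#' @param lean Whole-body lean toward the cone (deg) -> incline angle.
#' @param arm_phase Baseline arm-leg phase offset (rad); `pi` is normal
#'   anti-phase arm swing.
#' @param arm_leg_lag Additional pathological arm-leg phase lag (rad) ->
#'   temporal coordination parameters.
#' @param toe_clearance Peak toe height in swing (m).
#' @param turn_radius Initial distance of the pelvis from the cone (m).
#' @param com_wander Amplitude of slow radial COM wander (m).
#' @param noise_sd Marker noise SD (m); 1 mm matches optical capture.
#' @param rate Sampling rate (Hz).
#' @param inner_side Side performing the inner steps (`"left"` turns
#'   counter-clockwise).
#' @param lead_in,lead_out Quiet standing before/after the turn (s).
#' @param seed Integer seed making the trial reproducible.
#' @return A validated parameter list of class `puppet_params`.
#' @export
puppet_params <- function(cadence = 1.8, n_steps = 12,
                          step_length_inner = 0.40,
                          step_length_outer = 0.45,
                          step_width = 0.16, stance_fraction = 0.65,
                          amp_hip = 16, amp_knee = 25, amp_ankle = 15,
                          amp_shoulder = 10, amp_pelvis = 2,
                          amp_thorax = 17, yaw_offset_peak = 18,
                          lean = 6.3, arm_phase = pi, arm_leg_lag = 0,
                          toe_clearance = 0.03, turn_radius = 0.5,
                          com_wander = 0.01, noise_sd = 0.001,
                          rate = 100, inner_side = "left",
                          lead_in = 0.8, lead_out = 0.4, seed = 1L) {
  p <- list(cadence = cadence, n_steps = as.integer(n_steps),
            step_length_inner = step_length_inner,
            step_length_outer = step_length_outer,
            step_width = step_width, stance_fraction = stance_fraction,
            amp_hip = rep_len(amp_hip, 2), amp_knee = rep_len(amp_knee, 2),
            amp_ankle = rep_len(amp_ankle, 2),
            amp_shoulder = rep_len(amp_shoulder, 2),
            amp_pelvis = amp_pelvis, amp_thorax = amp_thorax,
            yaw_offset_peak = yaw_offset_peak, lean = lean,
            arm_phase = arm_phase, arm_leg_lag = arm_leg_lag,
            toe_clearance = toe_clearance, turn_radius = turn_radius,
            com_wander = com_wander, noise_sd = noise_sd, rate = rate,
            inner_side = match.arg(inner_side, c("left", "right")),
            lead_in = lead_in, lead_out = lead_out, seed = as.integer(seed))
  dims <- c("cadence", "step_length_inner", "step_length_outer",
            "step_width", "toe_clearance", "turn_radius", "rate")
  for (d in dims) if (p[[d]] <= 0) stop("`", d, "` must be positive")
  if (p$n_steps < 4L) stop("`n_steps` must be at least 4")
  if (p$stance_fraction <= 0.5 || p$stance_fraction >= 0.9)
    stop("`stance_fraction` must lie in (0.5, 0.9) for double support to exist")
  if (p$noise_sd < 0 || p$com_wander < 0) stop("noise/wander must be >= 0")
  class(p) <- "puppet_params"
  p
}

# smooth unit bump on [0,1]: 0 at the ends, 1 at `peak`; steep shoulders so
# threshold crossings stay within a frame of the programmed contact times
foot_bump <- function(tau, peak = 0.5) {
  u <- ifelse(tau < peak, (tau - peak) / peak, (tau - peak) / (1 - peak))
  z <- pmax(0, 1 - u^2)^0.75
  z[tau <= 0 | tau >= 1] <- 0
  z
}

#' Simulate one 360-degree turning trial
#'
#' Generates all 39 markers of the full-body model for a puppet walking a
#' circular path about a cone at the origin, together with a ground-truth
#' log of event times and programmed feature values. Trajectories are
#' deterministic given `params$seed`.
#'
#' Programmed (analytic) truth entries match the dials exactly; entries for
#' emergent quantities (ankle ROM, temporal coordination, COM path
#' statistics, steps inside the analysis window) are computed numerically
#' from the noise-free construction and marked in `truth_kind`.
#'
#' @param params A [puppet_params()].
#' @return List with `set` (a [marker_set()] with noise), `clean` (the
#'   noise-free set), `truth` (named list of ground-truth feature values on
#'   the feature-registry scale), `truth_kind`, `events` (data frame of true
#'   event times/frames) and `metadata` (a [trial_metadata()]).
#' @export
simulate_turn_trial <- function(params = puppet_params()) {
  p <- params
  stopifnot(inherits(p, "puppet_params"))
  set.seed(p$seed)
  rate <- p$rate
  f_str <- p$cadence / 2          # stride frequency (Hz)
  T_cyc <- 2 / p$cadence          # gait cycle (s)
  # rotation completes half a step period after the final contact so that
  # no true gait event sits exactly on the analysis-window boundary
  d_turn <- (p$n_steps + 0.5) / p$cadence
  T_tot <- p$lead_in + d_turn + p$lead_out
  tt <- seq(0, T_tot, by = 1 / rate)
  nf <- length(tt)
  d2r <- pi / 180

  # heading of the pelvis (rad), 0 -> 2*pi over the turn, with a small
  # terminal overshoot so measurement noise cannot leave the cumulative
  # heading fractionally below 360 degrees
  theta <- pmin(pmax((tt - p$lead_in) / d_turn, 0), 1.03) * 2 * pi
  ant <- cbind(-sin(theta), cos(theta))    # anterior unit
  nout <- cbind(cos(theta), sin(theta))    # outward radial unit
  th_at <- function(ti) pmin(pmax((ti - p$lead_in) / d_turn, 0), 1) * 2 * pi

  # ---- footfall chain (canonical: inner = left, counter-clockwise) ----
  w <- p$step_width
  P0 <- c(p$turn_radius, 0)
  q_left <- P0 - c(w / 2, 0)   # inner
  q_right <- P0 + c(w / 2, 0)
  tc <- p$lead_in + seq_len(p$n_steps) / p$cadence
  contacts <- list(
    left = data.frame(time = 0, x = q_left[1], y = q_left[2], dir = pi / 2),
    right = data.frame(time = 0, x = q_right[1], y = q_right[2], dir = pi / 2))
  prev <- q_right  # other foot's last contact when the inner foot steps first
  cur <- list(left = q_left, right = q_right)
  for (k in seq_len(p$n_steps)) {
    side <- if (k %% 2 == 1) "left" else "right"
    th_k <- th_at(tc[k])
    u <- c(-sin(th_k), cos(th_k)); nv <- c(cos(th_k), sin(th_k))
    sl <- if (side == "left") p$step_length_inner else p$step_length_outer
    lat <- if (side == "left") -w else w
    newp <- prev + sl * u + lat * nv
    contacts[[side]] <- rbind(contacts[[side]],
                              data.frame(time = tc[k], x = newp[1],
                                         y = newp[2], dir = th_k + pi / 2))
    prev <- newp
    cur[[side]] <- newp
  }

  # ---- foot marker trajectories ----
  s_f <- p$stance_fraction
  swing_dur <- (1 - s_f) * T_cyc
  L_foot <- 0.20
  amp_ankle <- p$amp_ankle  # c(inner, outer) = c(left, right) canonical
  foot_traj <- function(side) {
    cns <- contacts[[side]]
    h_toe <- p$toe_clearance
    ia <- if (side == "left") 1L else 2L
    h_heel <- p$toe_clearance + L_foot * sin(amp_ankle[ia] * d2r)
    x <- stats::approx(cns$time, cns$x, xout = tt, rule = 2)$y
    y <- stats::approx(cns$time, cns$y, xout = tt, rule = 2)$y
    ang <- stats::approx(cns$time, cns$dir, xout = tt, rule = 2)$y
    zt <- zh <- numeric(nf)
    tau_all <- rep(NA_real_, nf)
    for (i in seq_len(nrow(cns))[-1]) {
      hs_t <- cns$time[i]
      to_t <- hs_t - swing_dur
      sw <- tt > to_t & tt < hs_t
      tau <- (tt[sw] - to_t) / swing_dur
      tau_all[sw] <- tau
      ease <- (1 - cos(pi * tau)) / 2
      x[sw] <- cns$x[i - 1] + ease * (cns$x[i] - cns$x[i - 1])
      y[sw] <- cns$y[i - 1] + ease * (cns$y[i] - cns$y[i - 1])
      ang[sw] <- cns$dir[i - 1] + ease * (cns$dir[i] - cns$dir[i - 1])
      zh[sw] <- h_heel * foot_bump(tau, peak = 0.40)
      zt[sw] <- h_toe * foot_bump(tau, peak = 0.60)
      stance_prev <- tt >= cns$time[i - 1] & tt <= to_t
      x[stance_prev] <- cns$x[i - 1]; y[stance_prev] <- cns$y[i - 1]
      ang[stance_prev] <- cns$dir[i - 1]
    }
    last <- tt >= cns$time[nrow(cns)]
    x[last] <- cns$x[nrow(cns)]; y[last] <- cns$y[nrow(cns)]
    ang[last] <- cns$dir[nrow(cns)]
    fdir <- cbind(cos(ang), sin(ang))
    list(
      HEE = cbind(x - 0.5 * L_foot * fdir[, 1],
                  y - 0.5 * L_foot * fdir[, 2], zh),
      TOE = cbind(x + 0.5 * L_foot * fdir[, 1],
                  y + 0.5 * L_foot * fdir[, 2], zt),
      mid = cbind(x, y, (zh + zt) / 2),
      to_times = cns$time[-1] - swing_dur,
      hs_times = cns$time[-1])
  }
  ft <- list(left = foot_traj("left"), right = foot_traj("right"))

  # ---- pelvis ----
  x_ph <- 2 * pi * f_str * (tt - tc[1])  # common gait phase
  P_xy <- (ft$left$mid[, 1:2] + ft$right$mid[, 1:2]) / 2 +
    p$com_wander * sin(2 * pi * 0.45 * tt) * nout
  h_pelvis <- 0.95
  pitch_p <- p$amp_pelvis * d2r * cos(x_ph)
  ml3 <- cbind(cos(theta), sin(theta), 0)
  a3 <- cbind(cos(pitch_p) * ant[, 1], cos(pitch_p) * ant[, 2], sin(pitch_p))
  d3 <- cbind(sin(pitch_p) * ant[, 1], sin(pitch_p) * ant[, 2], -cos(pitch_p))
  P3 <- cbind(P_xy, h_pelvis)
  mk <- list()
  mk$LASI <- P3 - 0.12 * ml3 + 0.12 * a3
  mk$RASI <- P3 + 0.12 * ml3 + 0.12 * a3
  mk$LPSI <- P3 - 0.05 * ml3 - 0.10 * a3
  mk$RPSI <- P3 + 0.05 * ml3 - 0.10 * a3

  # ---- legs (hip/knee driven; ankle marker by forward kinematics) ----
  L_thigh <- 0.40; L_shank <- 0.40
  for (side in c("left", "right")) {
    ia <- if (side == "left") 1L else 2L
    sgn <- if (side == "left") -1 else 1
    ph_leg <- if (side == "left") 0 else pi
    alpha <- p$amp_hip[ia] * d2r * cos(x_ph - ph_leg)
    x_ms <- -pi * (1 - s_f)  # gait-phase offset of mid-swing (before HS)
    beta <- p$amp_knee[ia] * d2r * (1 - cos(x_ph - ph_leg - x_ms + pi))
    asi <- mk[[paste0(foot_prefix(side), "ASI")]]
    dir_t <- cos(alpha) * d3 + sin(alpha) * a3
    kne <- asi + L_thigh * dir_t
    dir_s <- cos(alpha - beta) * d3 + sin(alpha - beta) * a3
    ank <- kne + L_shank * dir_s
    pfx <- foot_prefix(side)
    mk[[paste0(pfx, "KNE")]] <- kne
    mk[[paste0(pfx, "THI")]] <- asi + 0.55 * L_thigh * dir_t +
      sgn * 0.04 * ml3
    mk[[paste0(pfx, "TIB")]] <- kne + 0.5 * L_shank * dir_s + sgn * 0.03 * ml3
    mk[[paste0(pfx, "ANK")]] <- ank
    mk[[paste0(pfx, "HEE")]] <- ft[[side]]$HEE
    mk[[paste0(pfx, "TOE")]] <- ft[[side]]$TOE
  }

  # ---- thorax, shoulders, arms ----
  yaw_off <- p$yaw_offset_peak * d2r * sin(x_ph)
  yaw_th <- theta + yaw_off
  ml_th <- cbind(cos(yaw_th), sin(yaw_th), 0)
  ant_th <- cbind(-sin(yaw_th), cos(yaw_th))
  pitch_t <- p$amp_thorax * d2r * cos(x_ph)
  a_th3 <- cbind(cos(pitch_t) * ant_th[, 1], cos(pitch_t) * ant_th[, 2],
                 sin(pitch_t))
  l_th3 <- cbind(-sin(pitch_t) * ant_th[, 1], -sin(pitch_t) * ant_th[, 2],
                 cos(pitch_t))
  d_th3 <- -l_th3
  C <- cbind(P_xy, 1.30)
  mk$C7 <- C + 0.225 * l_th3 - 0.05 * a_th3
  mk$T10 <- C - 0.225 * l_th3 - 0.05 * a_th3
  mk$CLAV <- C + 0.20 * l_th3 + 0.06 * a_th3
  mk$STRN <- C + 0.05 * l_th3 + 0.08 * a_th3
  mk$RBAK <- C + 0.15 * l_th3 - 0.08 * a_th3 + 0.05 * ml_th
  L_ua <- 0.28; L_fa <- 0.25
  for (side in c("left", "right")) {
    ia <- if (side == "left") 1L else 2L
    sgn <- if (side == "left") -1 else 1
    ph_leg <- if (side == "left") 0 else pi
    sho <- C + 0.21 * l_th3 + sgn * 0.18 * ml_th
    a_arm <- p$amp_shoulder[ia] * d2r *
      cos(x_ph - ph_leg + p$arm_phase + p$arm_leg_lag)
    dir_ua <- cos(a_arm) * d_th3 + sin(a_arm) * a_th3
    elb <- sho + L_ua * dir_ua
    a_fa <- a_arm + 30 * d2r
    dir_fa <- cos(a_fa) * d_th3 + sin(a_fa) * a_th3
    wri <- elb + L_fa * dir_fa
    pfx <- foot_prefix(side)
    mk[[paste0(pfx, "SHO")]] <- sho
    mk[[paste0(pfx, "UPA")]] <- sho + 0.6 * L_ua * dir_ua + sgn * 0.03 * ml_th
    mk[[paste0(pfx, "ELB")]] <- elb
    mk[[paste0(pfx, "FRM")]] <- elb + 0.5 * L_fa * dir_fa + sgn * 0.02 * ml_th
    mk[[paste0(pfx, "WRA")]] <- wri + sgn * 0.025 * ml_th
    mk[[paste0(pfx, "WRB")]] <- wri - sgn * 0.025 * ml_th
    mk[[paste0(pfx, "FIN")]] <- wri + 0.08 * dir_fa
  }

  # ---- head: programmed lean from the base-of-support reference ----
  B <- (mk$LHEE + mk$LTOE + mk$RHEE + mk$RTOE) / 4
  r_in <- cbind(-nout, 0)
  L_bh <- 1.60
  H <- B + L_bh * (sin(p$lean * d2r) * r_in +
                     cbind(0, 0, rep(cos(p$lean * d2r), nf)))
  mk$LFHD <- H - 0.07 * ml_th + 0.09 * cbind(ant_th, 0)
  mk$RFHD <- H + 0.07 * ml_th + 0.09 * cbind(ant_th, 0)
  mk$LBHD <- H - 0.07 * ml_th - 0.09 * cbind(ant_th, 0)
  mk$RBHD <- H + 0.07 * ml_th - 0.09 * cbind(ant_th, 0)

  model <- marker_model()
  mk <- mk[model$required_labels]

  # mirror for a right-inner (clockwise) turn: reflect X and swap sides
  if (p$inner_side == "right") {
    mk <- lapply(mk, function(m) { m[, 1] <- -m[, 1]; m })
    nm <- names(mk)
    sided <- !(nm %in% model$side_map$midline)  # RBAK is midline, stays put
    swapped <- nm
    swapped[sided & grepl("^L", nm)] <- sub("^L", "R", nm[sided & grepl("^L", nm)])
    swapped[sided & grepl("^R", nm)] <- sub("^R", "L", nm[sided & grepl("^R", nm)])
    names(mk) <- swapped
    mk <- mk[model$required_labels]
  }

  clean <- marker_set(mk, rate = rate)
  noisy <- clean
  if (p$noise_sd > 0) {
    for (lb in names(noisy$markers))
      noisy$markers[[lb]] <- noisy$markers[[lb]] +
        matrix(stats::rnorm(3 * nf, 0, p$noise_sd), nf, 3)
  }

  # ---- ground truth ----
  t10 <- p$lead_in + (10 / 360) * d_turn
  t360 <- p$lead_in + d_turn
  wf_true <- which(tt >= t10 & tt <= t360)
  truth <- list(
    steps_total = sum(tc >= t10 & tc <= t360),
    turn_duration = (350 / 360) * d_turn,
    step_width = 100 * w,
    step_length_inner = 100 * p$step_length_inner,
    step_length_outer = 100 * p$step_length_outer,
    single_support_inner = 100 * (1 - s_f),
    single_support_outer = 100 * (1 - s_f),
    double_support_inner = 100 * (2 * s_f - 1),
    double_support_outer = 100 * (2 * s_f - 1),
    stance_inner = 100 * s_f, stance_outer = 100 * s_f,
    rom_hip_inner = 2 * p$amp_hip[1], rom_hip_outer = 2 * p$amp_hip[2],
    rom_knee_inner = 2 * p$amp_knee[1], rom_knee_outer = 2 * p$amp_knee[2],
    rom_shoulder_inner = 2 * p$amp_shoulder[1],
    rom_shoulder_outer = 2 * p$amp_shoulder[2],
    rom_pelvis = 2 * p$amp_pelvis, rom_thorax = 2 * p$amp_thorax,
    toe_clearance_inner = 100 * p$toe_clearance,
    toe_clearance_outer = 100 * p$toe_clearance,
    max_anti_phase = p$yaw_offset_peak,
    incline_angle = p$lean)
  truth_kind <- stats::setNames(rep("programmed", length(truth)),
                                names(truth))

  # emergent truths, from the noise-free construction on the true window
  seg_true <- list(
    window = list(start_frame = wf_true[1], end_frame = wf_true[length(wf_true)],
                  duration = (350 / 360) * d_turn),
    events = list(
      left = list(heel_strikes = round(ft$left$hs_times * rate) + 1L,
                  toe_offs = round(ft$left$to_times * rate) + 1L),
      right = list(heel_strikes = round(ft$right$hs_times * rate) + 1L,
                   toe_offs = round(ft$right$to_times * rate) + 1L)),
    inner_foot = p$inner_side,
    outer_foot = setdiff(c("left", "right"), p$inner_side))
  rom_clean <- joint_rom_features(clean, seg_true)
  truth$rom_ankle_inner <- rom_clean$rom_ankle_inner
  truth$rom_ankle_outer <- rom_clean$rom_ankle_outer
  dt_clean <- temporal_coordination(clean, seg_true)
  truth <- c(truth, dt_clean)
  truth <- c(truth, com_features(com_trajectory(clean), seg_true, rate))
  truth_kind <- c(truth_kind, stats::setNames(
    rep("emergent", length(truth) - length(truth_kind)),
    setdiff(names(truth), names(truth_kind))))

  events <- rbind(
    data.frame(foot = "left", type = "heel_strike", time = ft$left$hs_times),
    data.frame(foot = "left", type = "toe_off", time = ft$left$to_times),
    data.frame(foot = "right", type = "heel_strike", time = ft$right$hs_times),
    data.frame(foot = "right", type = "toe_off", time = ft$right$to_times))
  if (p$inner_side == "right")
    events$foot <- ifelse(events$foot == "left", "right", "left")
  events$frame <- round(events$time * rate) + 1L
  events <- events[order(events$time), ]

  list(set = noisy, clean = clean, truth = truth, truth_kind = truth_kind,
       events = events,
       metadata = trial_metadata(subject_id = "puppet", group = "synthetic",
                                 inner_side = p$inner_side),
       params = p)
}

# ---- group archetypes ----

#' Group archetypes for cohort simulation
#'
#' Parameter offsets relative to the control puppet, reproducing the
#' directions reported for turning impairment: the PD archetype has a
#' shorter inner step length, wider step width, longer double support
#' (higher stance fraction), greater thorax ROM and smaller incline; the
#' freezer archetype additionally has a shorter outer step length, greater
#' inner-hip ROM, smaller inner-ankle foot-pitch amplitude, longer COM path
#' (more wander, more steps), smaller maximum anti-phase and a larger
#' arm-leg phase lag (longer contralateral temporal coordination).
#'
#' @param name `"control"`, `"pd"` or `"freezer"`.
#' @return List with `name`, `offsets` (named list added to control
#'   parameters) and `sd` (named list of between-subject SDs).
#' @export
group_archetype <- function(name = c("control", "pd", "freezer")) {
  name <- match.arg(name)
  base_sd <- list(cadence = 0.12, step_length_inner = 0.03,
                  step_length_outer = 0.03, step_width = 0.015,
                  stance_fraction = 0.02, amp_hip = 2, amp_knee = 2.5,
                  amp_ankle = 2.5, amp_shoulder = 2, amp_thorax = 2.5,
                  yaw_offset_peak = 3, lean = 1, arm_leg_lag = 0.15,
                  toe_clearance = 0.005, com_wander = 0.004)
  pd_off <- list(step_length_inner = -0.08, step_width = 0.035,
                 stance_fraction = 0.045, amp_thorax = 5, lean = -2.0,
                 cadence = -0.15, n_steps = 2)
  offsets <- switch(name,
    control = list(),
    pd = pd_off,
    freezer = utils::modifyList(pd_off, list(
      step_length_outer = -0.07,
      # ankle ROM is emergent (shank-over-foot); its freezer reduction is
      # planted through reduced inner knee flexion and foot-pitch amplitude
      amp_hip = c(4, 0), amp_knee = c(-8, 0), amp_ankle = c(-5, 0),
      # the arm peak leads its matched leg peak at baseline, so a negative
      # phase offset lengthens the contralateral coordination parameter
      com_wander = 0.012, yaw_offset_peak = -6, arm_leg_lag = -0.9,
      n_steps = 4)))
  list(name = name, offsets = offsets, sd = base_sd)
}

draw_subject_params <- function(arch, inner_side, seed) {
  base <- puppet_params()
  pars <- list()
  for (nm in names(arch$sd)) {
    off <- arch$offsets[[nm]]
    if (is.null(off)) off <- 0
    v <- unlist(base[[nm]])
    pars[[nm]] <- v + rep_len(off, length(v)) +
      stats::rnorm(length(v), 0, arch$sd[[nm]])
  }
  n_off <- arch$offsets$n_steps
  pars$n_steps <- base$n_steps + (if (is.null(n_off)) 0 else n_off) +
    sample(-1:1, 1)
  # clamp to validity
  pars$stance_fraction <- min(max(pars$stance_fraction, 0.55), 0.85)
  pars$step_length_inner <- max(pars$step_length_inner, 0.12)
  pars$step_length_outer <- max(pars$step_length_outer, 0.12)
  pars$step_width <- max(pars$step_width, 0.06)
  pars$toe_clearance <- max(pars$toe_clearance, 0.015)
  pars$cadence <- max(pars$cadence, 0.8)
  pars$com_wander <- max(pars$com_wander, 0)
  pars$amp_ankle <- pmax(pars$amp_ankle, 3)
  pars$amp_hip <- pmax(pars$amp_hip, 5)
  pars$amp_knee <- pmax(pars$amp_knee, 5)
  pars$amp_shoulder <- pmax(pars$amp_shoulder, 2)
  pars$amp_thorax <- pmax(pars$amp_thorax, 5)
  pars$yaw_offset_peak <- max(pars$yaw_offset_peak, 3)
  pars$lean <- max(pars$lean, 1)
  do.call(puppet_params, c(pars, list(inner_side = inner_side, seed = seed)))
}

#' Simulate a two-group cohort of turning subjects
#'
#' Draws per-subject puppet parameters from the archetype distributions,
#' records ground-truth feature values per subject (averaged over that
#' subject's trials is unnecessary: trials share the subject's parameters,
#' so the truth is identical across trials), and generates synthetic
#' covariates and clinical scores with planted linear links to the turning
#' features. The planted link coefficients are returned in `links` so
#' association recovery is checkable. Marker trials themselves are
#' regenerable deterministically per subject via [subject_trials()].
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param archetypes Character vector of two archetype names.
#' @param n_trials Trials per subject.
#' @param seed Cohort seed.
#' @return List with `subjects` (metadata data frame incl. clinical scores),
#'   `params` (list of per-subject [puppet_params()]), `truth` (data frame
#'   of ground-truth features) and `links`.
#' @export
simulate_cohort <- function(n_per_group, archetypes = c("control", "pd"),
                            n_trials = 3, seed = 1) {
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  stopifnot(length(archetypes) == 2)
  set.seed(seed)
  subs <- list(); pars <- list(); truths <- list()
  idx <- 0L
  for (g in archetypes) {
    arch <- group_archetype(g)
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      inner <- sample(c("left", "right"), 1)
      sseed <- sample.int(2^30, 1)
      sp <- draw_subject_params(arch, inner, sseed)
      pars[[sid]] <- sp
      tr <- simulate_turn_trial(sp)
      truths[[sid]] <- unlist(tr$truth)
      subs[[sid]] <- data.frame(
        subject_id = sid, group = g, inner_side = inner,
        age = round(stats::rnorm(1, 69, 5.5), 1),
        sex = sample(c("F", "M"), 1),
        height = round(stats::rnorm(1, 158, 8), 1),
        bmi = round(stats::rnorm(1, 24, 2.4), 1),
        n_trials = n_trials, seed = sseed)
    }
  }
  subjects <- do.call(rbind, subs)
  truth <- as.data.frame(do.call(rbind, truths))
  truth$subject_id <- subjects$subject_id

  # planted clinical links on true features (z-scored within cohort)
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  links <- list(
    updrs_total = list(feature = "dt_contra_outer", beta = 8, base = 48, sd = 6),
    updrs_iii = list(feature = "dt_contra_outer", beta = 5, base = 34, sd = 5),
    pigd = list(feature = "dt_contra_outer", beta = 0.35, base = 0.8, sd = 0.2),
    nfogq = list(feature = "step_length_outer", beta = -4, base = 8, sd = 3))
  for (nm in names(links)) {
    lk <- links[[nm]]
    subjects[[nm]] <- round(lk$base + lk$beta * zs(truth[[lk$feature]]) +
                              stats::rnorm(nrow(subjects), 0, lk$sd), 2)
  }
  list(subjects = subjects, params = pars, truth = truth, links = links)
}

#' Regenerate the marker trials of one cohort subject
#'
#' Trials differ only in marker noise; the trial index perturbs the seed
#' deterministically.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param subject_id Subject identifier.
#' @return List of `n_trials` simulation results (see
#'   [simulate_turn_trial()]).
#' @export
subject_trials <- function(cohort, subject_id) {
  sp <- cohort$params[[subject_id]]
  n <- cohort$subjects$n_trials[cohort$subjects$subject_id == subject_id]
  lapply(seq_len(n), function(i) {
    pi <- sp; pi$seed <- (sp$seed + 7919L * i) %% .Machine$integer.max
    simulate_turn_trial(pi)
  })
}

#' Extract measured features for a whole cohort
#'
#' Simulates each subject's trials and runs [extract_features()], returning
#' a feature table (one row per subject). The heavy marker-level route;
#' for statistics/classifier testing prefer [simulate_feature_table()].
#'
#' @param cohort Result of [simulate_cohort()].
#' @param ... Passed to [extract_features()].
#' @return Data frame of measured features with `subject_id` and `group`.
#' @export
cohort_features <- function(cohort, ...) {
  rows <- lapply(cohort$subjects$subject_id, function(sid) {
    trs <- subject_trials(cohort, sid)
    md <- trs[[1]]$metadata
    fv <- extract_features(lapply(trs, `[[`, "set"), md, ...)
    as.data.frame(as.list(fv))
  })
  out <- do.call(rbind, rows)
  out$subject_id <- cohort$subjects$subject_id
  out$group <- cohort$subjects$group
  out
}

# ---- direct feature-table simulator ----

#' Archetype effect sizes for the direct feature-table simulator
#'
#' Standardised group mean shifts (Cohen's d) on the features reported as
#' discriminative. `"pd"` plants large shifts (d = 2.2) on the five
#' PD-selected features; `"fog"` plants moderate shifts (d = 0.7) on the
#' six freezer-selected features. Signs follow the reported directions
#' (e.g. shorter step length = negative shift in the affected group).
#'
#' @param case `"pd"` or `"fog"`.
#' @return Named numeric vector of effect sizes.
#' @export
archetype_effect_sizes <- function(case = c("pd", "fog")) {
  case <- match.arg(case)
  if (case == "pd")
    c(step_length_inner = -2.2, step_width = 2.2, double_support_inner = 2.2,
      rom_thorax = 2.2, incline_angle = -2.2)
  else
    c(step_length_outer = -0.7, rom_hip_inner = 0.7, rom_ankle_inner = -0.7,
      com_total_distance = 0.7, max_anti_phase = -0.7, dt_contra_outer = 0.7)
}

#' Simulate a two-group feature table directly
#'
#' Multivariate-normal features with unit within-group SD, specified group
#' mean shifts (Cohen's d) and a common correlation structure; the direct
#' input for the selection and classification modules.
#'
#' @param n_per_group Samples per group.
#' @param effect_sizes Named numeric vector of standardised mean shifts for
#'   group 1 relative to group 0; names become feature columns.
#' @param n_noise Additional unshifted noise features (`noise1`, ...).
#' @param correlation Scalar exchangeable correlation or a full correlation
#'   matrix over all features.
#' @param seed Seed.
#' @return List with `features` (data frame), `labels` (0/1 integer vector)
#'   and `effect_sizes`.
#' @export
simulate_feature_table <- function(n_per_group, effect_sizes,
                                   n_noise = 0, correlation = 0,
                                   seed = 1) {
  set.seed(seed)
  nm <- c(names(effect_sizes),
          if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  d <- c(unname(effect_sizes), rep(0, n_noise))
  p <- length(d)
  R <- if (is.matrix(correlation)) correlation else
    matrix(correlation, p, p) + diag(1 - correlation, p)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is not positive definite")
  L <- chol(R)
  n <- 2 * n_per_group
  Z <- matrix(stats::rnorm(n * p), n, p) %*% L
  labels <- rep(0:1, each = n_per_group)
  X <- Z + outer(labels, d)
  colnames(X) <- nm
  list(features = as.data.frame(X), labels = as.integer(labels),
       effect_sizes = stats::setNames(d, nm))
}
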