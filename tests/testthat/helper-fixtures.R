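# Builders for small analytic marker fixtures used across test files.

# marker set with all 39 labels at fixed positions (standing still),
# facing +Y (pelvic left->right vector along +X)
standing_set <- function(n_frames = 50, rate = 100) {
  model <- marker_model()
  base <- list(
    LASI = c(-0.12, 0.10, 0.95), RASI = c(0.12, 0.10, 0.95),
    LPSI = c(-0.05, -0.10, 0.95), RPSI = c(0.05, -0.10, 0.95),
    LHEE = c(-0.10, -0.10, 0.02), RHEE = c(0.10, -0.10, 0.02),
    LTOE = c(-0.10, 0.10, 0.02), RTOE = c(0.10, 0.10, 0.02),
    LANK = c(-0.10, -0.05, 0.08), RANK = c(0.10, -0.05, 0.08),
    LKNE = c(-0.10, 0.0, 0.50), RKNE = c(0.10, 0.0, 0.50),
    LTHI = c(-0.14, 0.02, 0.70), RTHI = c(0.14, 0.02, 0.70),
    LTIB = c(-0.13, -0.02, 0.30), RTIB = c(0.13, -0.02, 0.30),
    LSHO = c(-0.18, 0.0, 1.50), RSHO = c(0.18, 0.0, 1.50),
    LUPA = c(-0.21, 0.0, 1.35), RUPA = c(0.21, 0.0, 1.35),
    LELB = c(-0.22, 0.0, 1.22), RELB = c(0.22, 0.0, 1.22),
    LFRM = c(-0.23, 0.03, 1.10), RFRM = c(0.23, 0.03, 1.10),
    LWRA = c(-0.24, 0.06, 1.00), RWRA = c(0.24, 0.06, 1.00),
    LWRB = c(-0.20, 0.06, 1.00), RWRB = c(0.20, 0.06, 1.00),
    LFIN = c(-0.22, 0.12, 0.95), RFIN = c(0.22, 0.12, 0.95),
    LFHD = c(-0.07, 0.09, 1.70), RFHD = c(0.07, 0.09, 1.70),
    LBHD = c(-0.07, -0.09, 1.70), RBHD = c(0.07, -0.09, 1.70),
    C7 = c(0, -0.07, 1.55), T10 = c(0, -0.09, 1.25),
    CLAV = c(0, 0.07, 1.50), STRN = c(0, 0.09, 1.30),
    RBAK = c(0.05, -0.10, 1.40))
  mk <- lapply(base, function(pos)
    matrix(rep(pos, each = n_frames), n_frames, 3))
  marker_set(mk[model$required_labels], rate = rate)
}

# rotate a marker set about the global Z axis by `deg` and translate by `dxy`
transform_set <- function(set, deg = 0, dxy = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- set
  for (lb in names(set$markers)) {
    m <- set$markers[[lb]]
    m[, 1:2] <- m[, 1:2] %*% t(R)
    m[, 1] <- m[, 1] + dxy[1]; m[, 2] <- m[, 2] + dxy[2]
    out$markers[[lb]] <- m
  }
  out
}

# a fast, quiet puppet for tests that only need structure, not accuracy
quick_params <- function(...) {
  puppet_params(noise_sd = 0, lead_in = 0.5, lead_out = 0.3, ...)
}

# segmentation with hand-specified window/events (bypasses detection)
manual_seg <- function(start_frame, end_frame, duration,
                       left_hs = integer(), left_to = integer(),
                       right_hs = integer(), right_to = integer(),
                       inner = "left") {
  list(window = list(start_frame = start_frame, end_frame = end_frame,
                     duration = duration),
       events = list(left = list(heel_strikes = left_hs, toe_offs = left_to),
                     right = list(heel_strikes = right_hs,
                                  toe_offs = right_to)),
       inner_foot = inner, outer_foot = setdiff(c("left", "right"), inner))
}
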