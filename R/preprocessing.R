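#' Low-pass filter specification
#'
#' Defaults follow standard clinical gait practice: a fourth-order
#' Butterworth low-pass at 10 Hz applied forward and backward (zero phase
#' lag). The order refers to the single-pass coefficient order; the
#' effective dual-pass attenuation is the squared single-pass magnitude
#' response, so the -6 dB point of the dual-pass filter sits slightly below
#' the nominal cutoff (about 8 Hz for order 4 at 10 Hz). No cutoff
#' correction factor is applied.
#'
#' @param order Filter order (even when `zero_phase`).
#' @param cutoff_hz Cut-off frequency in Hz; must be below the Nyquist rate.
#' @param zero_phase Apply forward-backward for zero phase lag.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 10, zero_phase = TRUE) {
  if (order < 1 || order != round(order)) stop("`order` must be a positive integer")
  if (zero_phase && order %% 2 != 0)
    stop("`order` must be even for a zero-phase (dual-pass) filter")
  if (cutoff_hz <= 0) stop("`cutoff_hz` must be positive")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Butterworth low-pass coefficients
#'
#' Designs digital low-pass Butterworth coefficients by bilinear transform
#' of the analog prototype (poles on the unit circle at odd multiples of
#' pi/2n, cutoff pre-warped). Returns transfer-function coefficients `b`
#' (numerator) and `a` (denominator), `a[1] = 1`, exact unit DC gain.
#'
#' @param order Filter order.
#' @param cutoff_hz Cut-off frequency (Hz).
#' @param rate Sampling rate (Hz).
#' @return List with numeric vectors `b` and `a` of length `order + 1`.
#' @export
butter_lowpass <- function(order, cutoff_hz, rate) {
  if (cutoff_hz >= rate / 2)
    stop("cutoff must be below the Nyquist frequency (rate/2)")
  n <- as.integer(order)
  # analog prototype poles (unit cutoff), left half plane
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  wc <- 2 * rate * tan(pi * cutoff_hz / rate)   # pre-warped analog cutoff
  ps <- pa * wc
  fs2 <- 2 * rate
  # bilinear transform: pole z_k = (fs2 + ps)/(fs2 - ps); n zeros at z = -1
  pz <- (fs2 + ps) / (fs2 - ps)
  poly_from_roots <- function(r) {
    coefs <- 1 + 0i
    for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
    coefs
  }
  a <- Re(poly_from_roots(pz))
  b <- Re(choose(n, 0:n))
  # enforce exact unit DC gain
  b <- b * (sum(a) / sum(b))
  list(b = b, a = a)
}

# steady-state initial filter state for a unit-step input (direct form II
# transposed), so edge transients vanish exactly for locally constant input
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 1L) comp[cbind(2:n, 1:(n - 1L))] <- 1
  solve(diag(n) - t(comp), b[-1] - a[-1] * b[1])
}

# direct-form-II-transposed IIR applied down the rows of a matrix
iir_filter_matrix <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); nc <- ncol(x)
  nt <- length(a)
  y <- matrix(0, n, nc)
  z <- if (is.null(zi)) matrix(0, nt - 1L, nc) else zi %o% x[1, ]
  for (t in seq_len(n)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (nt > 2L)
      for (j in seq_len(nt - 2L))
        z[j, ] <- b[j + 1L] * xt + z[j + 1L, ] - a[j + 1L] * yt
    z[nt - 1L, ] <- b[nt] * xt - a[nt] * yt
    y[t, ] <- yt
  }
  y
}

# zero-phase forward-backward filtering with odd-reflection edge padding
filtfilt_matrix <- function(b, a, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= npad + 1L)
    stop("signal too short for the filter warm-up (need > ",
         npad + 1L, " frames)")
  head_pad <- 2 * matrix(x[1, ], npad, ncol(x), byrow = TRUE) -
    x[(npad + 1L):2, , drop = FALSE]
  tail_pad <- 2 * matrix(x[n, ], npad, ncol(x), byrow = TRUE) -
    x[(n - 1L):(n - npad), , drop = FALSE]
  xp <- rbind(head_pad, x, tail_pad)
  zi <- lfilter_zi(b, a)
  y <- iir_filter_matrix(b, a, xp, zi = zi)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- iir_filter_matrix(b, a, y, zi = zi)
  y <- y[nrow(y):1, , drop = FALSE]
  y[(npad + 1L):(npad + n), , drop = FALSE]
}

#' Zero-phase low-pass filter a marker set
#'
#' Each marker coordinate is filtered independently. With
#' `spec$zero_phase` the coefficients are applied forward then backward,
#' which doubles the attenuation and cancels the phase lag; reflective
#' padding suppresses edge transients. Gaps must be filled first (see
#' [interpolate_gaps()]): frames still flagged missing cause an error.
#'
#' @param set A [marker_set()].
#' @param spec A [filter_spec()].
#' @return A filtered [marker_set()].
#' @export
filter_lowpass <- function(set, spec = filter_spec()) {
  stopifnot(inherits(set, "marker_set"), inherits(spec, "filter_spec"))
  if (any(set$missing_mask))
    stop("unfilled gaps present; run interpolate_gaps() before filtering")
  co <- butter_lowpass(spec$order, spec$cutoff_hz, set$rate)
  X <- do.call(cbind, set$markers)
  Y <- if (spec$zero_phase) filtfilt_matrix(co$b, co$a, X) else
    iir_filter_matrix(co$b, co$a, X)
  out <- set
  for (j in seq_along(set$markers)) {
    m <- Y[, (3L * (j - 1L) + 1L):(3L * j), drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    out$markers[[j]] <- m
  }
  out
}

#' Fill short marker gaps by cubic interpolation
#'
#' Gaps of at most `max_gap_frames` consecutive missing frames are filled by
#' a natural cubic spline through the observed samples of that coordinate;
#' longer gaps (and gaps touching the trial boundary) remain flagged so
#' downstream operations reject the affected frames instead of trusting
#' extrapolated positions.
#'
#' @param set A [marker_set()].
#' @param max_gap_frames Longest gap (frames) that may be filled (default 10,
#'   i.e. 0.1 s at 100 Hz).
#' @return A [marker_set()] with short gaps filled and the missing mask
#'   updated.
#' @export
interpolate_gaps <- function(set, max_gap_frames = 10) {
  stopifnot(inherits(set, "marker_set"))
  out <- set
  for (lb in names(set$markers)) {
    miss <- set$missing_mask[, lb]
    if (!any(miss)) next
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    fill <- logical(set$n_frames)
    for (r in which(runs$values)) {
      interior <- starts[r] > 1L && ends[r] < set$n_frames
      if (interior && runs$lengths[r] <= max_gap_frames)
        fill[starts[r]:ends[r]] <- TRUE
    }
    if (!any(fill)) next
    obs <- which(!miss)
    m <- out$markers[[lb]]
    for (d in 1:3) {
      sf <- stats::splinefun(obs, m[obs, d], method = "natural")
      m[fill, d] <- sf(which(fill))
    }
    out$markers[[lb]] <- m
    out$missing_mask[fill, lb] <- FALSE
  }
  out
}
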