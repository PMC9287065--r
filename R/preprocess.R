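#' Convert device pixels to millimetres
#'
#' The tablet records positions in device pixels at a fixed pixel density
#' (326 pixels per inch for the device used here); kinematic quantities are
#' reported in millimetres. The conversion is linear:
#' `mm = px * 25.4 / ppi`.
#'
#' @param px Value(s) in device pixels.
#' @param ppi Pixels per inch (> 0).
#' @return Value(s) in mm.
#' @examples
#' px_to_mm(326)  # one inch = 25.4 mm
#' @export
px_to_mm <- function(px, ppi = 326) {
  if (!is.numeric(ppi) || length(ppi) != 1 || is.na(ppi) || ppi <= 0) {
    stopf("`ppi` must be a positive number", class = "swipekin_config_error")
  }
  px * 25.4 / ppi
}

#' @rdname px_to_mm
#' @param mm Value(s) in millimetres.
#' @export
mm_to_px <- function(mm, ppi = 326) {
  if (!is.numeric(ppi) || length(ppi) != 1 || is.na(ppi) || ppi <= 0) {
    stopf("`ppi` must be a positive number", class = "swipekin_config_error")
  }
  mm * ppi / 25.4
}

#' Resample a swipe onto a uniform grid in millimetres
#'
#' Device timestamps are nominally 60 Hz but can jitter. Positions are
#' linearly interpolated onto a uniform grid spanning `[t_begin, t_end]`
#' with `round(span * fs) + 1` points. When the recorded sampling is already
#' uniform to within `jitter_tol * dt`, the original samples pass through
#' unchanged (no resampling noise is introduced). Pixel coordinates are
#' converted to mm, and the raw (pre-filter) start and end positions are
#' kept so the target-distance covariate can use the recorded endpoints.
#'
#' @param swipe A `raw_swipe`.
#' @param fs Sampling rate in Hz (default 60).
#' @param ppi Pixels per inch for unit conversion.
#' @param jitter_tol Fraction of the nominal sample interval below which
#'   timing jitter is ignored (default 0.1).
#' @return A `trajectory`: list with `t` (s, starting at 0), `x`, `y` (mm),
#'   `raw_start`, `raw_end` (mm), and identifiers.
#' @export
regularise_sampling <- function(swipe, fs = 60, ppi = 326, jitter_tol = 0.1) {
  stopifnot(inherits(swipe, "raw_swipe"))
  ev <- swipe$events
  if (nrow(ev) < 5) {
    stopf("swipe has fewer than 5 samples", class = "swipekin_too_short")
  }
  t <- ev$t - ev$t[1]
  if (any(diff(t) <= 0)) {
    stopf("timestamps must be strictly increasing within a gesture")
  }
  x <- px_to_mm(ev$x, ppi)
  y <- px_to_mm(ev$y, ppi)
  dt <- 1 / fs
  span <- t[length(t)]
  n_grid <- round(span * fs) + 1
  if (n_grid < 5) {
    stopf("swipe spans fewer than 5 grid points at %g Hz", fs, class = "swipekin_too_short")
  }
  if (length(t) == n_grid && max(abs(diff(t) - dt)) <= jitter_tol * dt) {
    tg <- t; xg <- x; yg <- y
  } else {
    tg <- seq(0, span, length.out = n_grid)
    xg <- approx(t, x, xout = tg, rule = 2)$y
    yg <- approx(t, y, xout = tg, rule = 2)$y
  }
  structure(
    list(participant_id = swipe$participant_id, gesture_id = swipe$gesture_id,
         t = tg, x = xg, y = yg, fs = fs,
         raw_start = c(x[1], y[1]), raw_end = c(x[length(x)], y[length(y)])),
    class = "trajectory"
  )
}

#' Zero-phase low-pass Butterworth filter
#'
#' Designs a Butterworth low-pass filter of the given order and applies it
#' forward and backward, which doubles the attenuation and cancels the phase
#' lag -- the conventional smoother for movement position data. Edge
#' transients are controlled by odd-reflection padding of length
#' `3 * order` on both ends. Series too short for that padding are returned
#' unfiltered with a warning rather than dropped: the only hard length rule
#' in the pipeline is the five-sample minimum.
#'
#' The amplitude gain of the double pass at frequency `f` is the squared
#' single-pass magnitude, `1 / (1 + (f / fc)^(2 * order))`, so DC passes at
#' gain 1 and the cutoff at gain 0.5.
#'
#' @param series Numeric vector (a position coordinate).
#' @param fs Sampling rate, Hz.
#' @param fc Cutoff frequency, Hz (must be below `fs / 2`).
#' @param order Filter order (default 4).
#' @return Filtered vector, same length.
#' @export
lowpass_zero_phase <- function(series, fs = 60, fc = 8, order = 4) {
  assert_numeric(series, "series")
  if (fc >= fs / 2) {
    stopf("cutoff fc = %g must be below the Nyquist frequency %g", fc, fs / 2,
          class = "swipekin_config_error")
  }
  n <- length(series)
  n_pad <- 3L * order
  if (n < n_pad + 1L) {
    warnf("series of length %d is too short for zero-phase filtering (needs > %d); passing through unfiltered",
          n, n_pad)
    return(series)
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # one causal pass, started at the steady state of the first sample so no
  # start-up transient leaks past the reflection padding
  pass <- function(x) {
    as.numeric(signal::filter(bf$b, bf$a, x,
                              init.x = rep(x[1], length(bf$b) - 1L),
                              init.y = rep(x[1], length(bf$a) - 1L)))
  }
  pre <- 2 * series[1] - series[(n_pad + 1L):2L]
  post <- 2 * series[n] - series[(n - 1L):(n - n_pad)]
  padded <- c(pre, series, post)
  fwd <- pass(padded)
  bwd <- rev(pass(rev(fwd)))
  bwd[(n_pad + 1L):(n_pad + n)]
}

#' Five-point-stencil derivative
#'
#' Interior samples use the fourth-order central stencil
#' `(-f[i+2] + 8 f[i+1] - 8 f[i-1] + f[i-2]) / (12 dt)`, exact for
#' polynomials up to degree four. The first and last two samples use
#' second-order one-sided / three-point differences so the derivative is
#' defined over the full touch interval.
#'
#' @param series Numeric vector of length >= 5.
#' @param dt Sample interval in seconds (> 0).
#' @return Derivative vector, same length as `series`.
#' @export
derivative_five_point <- function(series, dt) {
  assert_numeric(series, "series")
  n <- length(series)
  if (n < 5) stopf("five-point derivative needs at least 5 samples, got %d", n)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stopf("`dt` must be a positive scalar")
  f <- series
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (-f[i + 2] + 8 * f[i + 1] - 8 * f[i - 1] + f[i - 2]) / (12 * dt)
  d[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * dt)
  d[2] <- (f[3] - f[1]) / (2 * dt)
  d[n - 1] <- (f[n] - f[n - 2]) / (2 * dt)
  d[n] <- (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / (2 * dt)
  d
}

#' Speed from velocity components
#'
#' Elementwise Euclidean norm of the x- and y-velocity vectors.
#'
#' @param vx,vy Velocity components, mm/s, equal length.
#' @return Non-negative speed vector, mm/s.
#' @export
speed_from_velocity <- function(vx, vy) {
  if (length(vx) != length(vy)) stopf("`vx` and `vy` must have equal length")
  sqrt(vx^2 + vy^2)
}

#' Filter a trajectory and derive its velocity profile
#'
#' Applies the zero-phase low-pass filter to x and y independently, then
#' differentiates each with the five-point stencil and combines the
#' components into speed. All outputs have the trajectory's length.
#'
#' @param traj A `trajectory` from [regularise_sampling()].
#' @param fc,order Filter cutoff (Hz) and order; see [lowpass_zero_phase()].
#' @return A `velocity_profile` extending the trajectory with filtered
#'   `x`, `y` and `vx`, `vy`, `speed`.
#' @export
velocity_profile <- function(traj, fc = 8, order = 4) {
  stopifnot(inherits(traj, "trajectory"))
  dt <- 1 / traj$fs
  xf <- lowpass_zero_phase(traj$x, fs = traj$fs, fc = fc, order = order)
  yf <- lowpass_zero_phase(traj$y, fs = traj$fs, fc = fc, order = order)
  vx <- derivative_five_point(xf, dt)
  vy <- derivative_five_point(yf, dt)
  out <- traj
  out$x <- xf
  out$y <- yf
  out$vx <- vx
  out$vy <- vy
  out$speed <- speed_from_velocity(vx, vy)
  class(out) <- c("velocity_profile", "trajectory")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<%s> %s / %s: %d samples, %.3f s, %.1f Hz\n",
              class(x)[1], x$participant_id %||% "?", x$gesture_id %||% "?",
              length(x$t), x$t[length(x$t)] - x$t[1], x$fs))
  invisible(x)
}
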