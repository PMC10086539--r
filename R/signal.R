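#' Fit a smoothing spline to a sampled channel
#'
#' Cubic smoothing spline with the smoothing parameter chosen by
#' generalized cross-validation (unless `spar` is given). Splining, rather
#' than filtering, avoids the end effects that recursive filters produce
#' on non-cyclic records; velocity and acceleration are taken analytically
#' from the spline, never by finite differences of raw samples.
#'
#' @param time Uniform, strictly increasing sample times (s); >= 8 samples.
#' @param values Channel values.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects it by GCV.
#' @param nknots Optional knot count; by default every sample is a knot up
#'   to 2000 samples, 2000 knots beyond that.
#' @return An object of class `smoothed_signal`.
#' @export
fit_smoothing_spline <- function(time, values, spar = NULL, nknots = NULL) {
  if (length(time) < 8L)
    stop("need at least 8 samples to fit a smoothing spline", call. = FALSE)
  if (length(values) != length(time))
    stop("`values` must match `time` in length", call. = FALSE)
  .check_uniform_time(time, "smoothing input")
  n <- length(time)
  all_knots <- is.null(nknots) && n <= 2000L
  args <- list(x = time, y = values, cv = FALSE, keep.data = FALSE,
               all.knots = all_knots)
  if (!all_knots) args$nknots <- nknots %||% 2000L
  if (!is.null(spar)) args$spar <- spar
  fit <- suppressWarnings(do.call(stats::smooth.spline, args))
  res <- stats::predict(fit, time)$y - values
  structure(list(fit = fit, range = range(time), n = n,
                 rms_residual = sqrt(mean(res^2))),
            class = "smoothed_signal")
}

#' Evaluate a smoothed signal or its derivatives
#'
#' @param object A `smoothed_signal`.
#' @param t Evaluation times (s).
#' @param deriv Derivative order 0, 1 or 2.
#' @param ... Unused.
#' @return Numeric vector of values.
#' @export
predict.smoothed_signal <- function(object, t, deriv = 0L, ...) {
  if (!deriv %in% 0:2) stop("`deriv` must be 0, 1 or 2", call. = FALSE)
  stats::predict(object$fit, t, deriv = deriv)$y
}

#' @export
print.smoothed_signal <- function(x, ...) {
  cat(sprintf("Smoothing spline over [%.4f, %.4f] s (%d samples, RMS residual %.3g)\n",
              x$range[1], x$range[2], x$n, x$rms_residual))
  invisible(x)
}

#' Detect strike onset
#'
#' Onset is the first time the fore--aft head velocity exceeds
#' `max(frac * peak, floor)` and stays above it for at least `hold`
#' seconds, backtracked to the most recent zero crossing or local minimum
#' of the velocity.
#'
#' @param time Evaluation grid (s), uniform.
#' @param v Smoothed fore--aft head velocity on that grid (m s^-1).
#' @param min_peak Minimum peak velocity for a strike to be declared
#'   (default 0.1 m s^-1).
#' @param frac Fraction of the peak velocity used as threshold (default 0.05).
#' @param floor Absolute velocity floor for the threshold (default
#'   0.05 m s^-1).
#' @param hold Minimum time above threshold (default 0.010 s).
#' @return Onset time in seconds.
#' @export
detect_onset <- function(time, v, min_peak = 0.1, frac = 0.05,
                         floor = 0.05, hold = 0.010) {
  stopifnot(length(time) == length(v), length(time) >= 2L)
  peak <- max(v)
  if (!is.finite(peak) || peak < min_peak)
    stop(sprintf("no strike detected: peak fore-aft velocity %.3f m/s is below %.3f m/s",
                 peak, min_peak), call. = FALSE)
  thr <- max(frac * peak, floor)
  dt <- time[2] - time[1]
  hold_n <- max(1L, as.integer(round(hold / dt)))
  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= hold_n)
  if (!length(ok))
    stop("no strike detected: velocity never stays above threshold", call. = FALSE)
  i <- starts[ok[1L]]
  j <- i
  while (j > 1L && v[j - 1L] > 0 && v[j - 1L] < v[j]) j <- j - 1L
  if (j > 1L && v[j - 1L] <= 0) j <- j - 1L
  time[j]
}

#' Detect the end of forward progress
#'
#' The first time after the velocity peak at which the fore--aft head
#' velocity is non-positive; if it never returns to zero, the last sample
#' is used and flagged.
#'
#' @inheritParams detect_onset
#' @param t_onset Onset time from [detect_onset()].
#' @return A list with `t_end_forward` (s) and logical `end_warning`.
#' @export
detect_end_forward <- function(time, v, t_onset) {
  sel <- which(time >= t_onset)
  if (!length(sel)) stop("onset is beyond the record", call. = FALSE)
  ipk <- sel[which.max(v[sel])]
  after <- which(time > time[ipk] & v <= 0)
  if (length(after)) {
    list(t_end_forward = time[after[1L]], end_warning = FALSE)
  } else {
    warning("fore-aft head velocity never returned to zero; using the last sample as end of forward progress")
    list(t_end_forward = time[length(time)], end_warning = TRUE)
  }
}

# Refine a velocity zero crossing near a threshold crossing at index i by
# fitting a local quadratic and taking its root. A smooth stop (or start)
# approaches zero velocity tangentially, so the sample-level first
# crossing is ill-conditioned; the local fit is exact for a quadratic
# approach and averages noise over a slope- and noise-adaptive window.
.quadroot_refine <- function(time, v, i, thr, sig, rising) {
  dt <- time[2] - time[1]
  n <- length(v)
  tc <- time[i]
  slope <- (v[min(i + 1L, n)] - v[max(i - 1L, 1L)]) / (2 * dt)
  s <- abs(slope)
  if (s < 1e-6) s <- thr / 0.01
  ttz <- 2 * thr / s                       # time to zero under tangency
  inner <- min(max(1.1 * ttz, 6 * sig / s, 0.008), 0.04)
  outer <- min(max(ttz / 2, 2 * sig / s, 0.004), 0.04)
  sel <- if (rising) time >= tc - inner & time <= tc + outer
  else time >= tc - outer & time <= tc + inner
  if (sum(sel) < 5L) return(NA_real_)
  ft <- time[sel] - tc
  cf <- stats::coef(stats::lm(v[sel] ~ ft + I(ft^2)))
  disc <- cf[[2]]^2 - 4 * cf[[3]] * cf[[1]]
  if (!is.finite(disc) || disc < 0) return(NA_real_)
  rts <- (-cf[[2]] + c(-1, 1) * sqrt(disc)) / (2 * cf[[3]])
  if (rising) {
    rts <- rts[rts <= 0 & rts > -2 * inner]
    if (!length(rts)) return(NA_real_)
    tc + max(rts)
  } else {
    rts <- rts[rts >= 0 & rts < 2 * inner]
    if (!length(rts)) return(NA_real_)
    tc + min(rts)
  }
}

#' Detect the strike window
#'
#' Runs [detect_onset()] then [detect_end_forward()] on the same velocity
#' signal. With `refine = TRUE` (the default) both event times are then
#' refined by a local quadratic fit around the threshold crossings: a
#' smooth strike starts and stops with near-zero acceleration, so the
#' velocity approaches zero tangentially and the raw first-crossing time
#' is noise-sensitive; the quadratic root is exact for such a tangential
#' approach. The refinement window adapts to the local slope and to the
#' velocity noise level estimated from the pre-strike quiet segment.
#'
#' @inheritParams detect_onset
#' @param refine Logical; apply the quadratic-root refinement.
#' @return A [strike_events()].
#' @export
detect_strike_events <- function(time, v, min_peak = 0.1, frac = 0.05,
                                 floor = 0.05, hold = 0.010, refine = TRUE) {
  t0 <- detect_onset(time, v, min_peak = min_peak, frac = frac,
                     floor = floor, hold = hold)
  e <- detect_end_forward(time, v, t0)
  t1 <- e$t_end_forward
  if (refine) {
    dt <- time[2] - time[1]
    thr <- max(frac * max(v), floor)
    quiet <- time < t0 - 0.02
    sig <- if (sum(quiet) >= 8L) stats::sd(v[quiet]) else 0
    hold_n <- max(1L, as.integer(round(hold / dt)))
    r <- rle(v > thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= hold_n)
    if (length(ok)) {
      t0r <- .quadroot_refine(time, v, starts[ok[1L]], thr, sig, rising = TRUE)
      if (is.finite(t0r)) t0 <- t0r
    }
    ipk <- which.max(v)
    below <- which(time > time[ipk] & v <= thr)
    if (length(below) && !e$end_warning) {
      t1r <- .quadroot_refine(time, v, below[1L], thr, sig, rising = FALSE)
      if (is.finite(t1r) && t1r > t0) t1 <- t1r
    }
  }
  strike_events(t0, t1, end_warning = e$end_warning)
}
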