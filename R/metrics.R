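#' Convert force to body weights
#'
#' @param force_N Force in newtons (any shape).
#' @param mass_kg Subject mass in kg (> 0).
#' @param g Gravitational acceleration (default 9.81 m s^-2).
#' @return Force in body weights (unitless): `force_N / (mass_kg * g)`.
#' @export
to_body_weights <- function(force_N, mass_kg, g = 9.81) {
  if (!is.finite(mass_kg) || mass_kg <= 0)
    stop("`mass_kg` must be positive", call. = FALSE)
  force_N / (mass_kg * g)
}

#' Fore--aft impulse
#'
#' Trapezoidal integral of the fore--aft force over the strike window
#' (onset to end of forward progress), signed, in N s.
#'
#' @param time Sample times (s).
#' @param F_fa Fore--aft force (N) on the same grid.
#' @param events Optional [strike_events()]; when given, integration is
#'   restricted to `[t_onset, t_end_forward]`.
#' @return Impulse in N s.
#' @export
fore_aft_impulse <- function(time, F_fa, events = NULL) {
  stopifnot(length(time) == length(F_fa))
  if (!is.null(events)) {
    sel <- time >= events$t_onset & time <= events$t_end_forward
    time <- time[sel]; F_fa <- F_fa[sel]
  }
  if (length(time) < 2L)
    stop("empty strike window: nothing to integrate", call. = FALSE)
  pracma::trapz(time, F_fa)
}

#' Slip statistic
#'
#' Per-sample Coulomb slip test: the ratio `r = |F_fa| / F_v` is compared
#' with the substrate friction coefficient; slip is predicted wherever
#' `r > mu`. Samples with vertical force below `fv_floor` are excluded
#' from both counts (the ratio is unstable near zero vertical load) and
#' reported as excluded.
#'
#' @param F_fa,F_v Fore--aft and vertical force (N) on a common grid.
#' @param mu Friction coefficient.
#' @param time Optional sample times, required when `events` is given.
#' @param events Optional [strike_events()] restricting the window.
#' @param fv_floor Vertical-force validity floor in newtons (default 0;
#'   the pipeline uses 0.05 body weights).
#' @return List with `max_fa_v_ratio`, `pct_above_slip` (0--100),
#'   `n_valid`, `n_excluded`.
#' @export
slip_fraction <- function(F_fa, F_v, mu, time = NULL, events = NULL,
                          fv_floor = 0) {
  stopifnot(length(F_fa) == length(F_v))
  if (!is.null(events)) {
    if (is.null(time)) stop("`time` is required with `events`", call. = FALSE)
    sel <- time >= events$t_onset & time <= events$t_end_forward
    F_fa <- F_fa[sel]; F_v <- F_v[sel]
  }
  valid <- F_v >= fv_floor
  if (!any(valid))
    stop("all samples excluded by the vertical-force floor; slip statistic undefined",
         call. = FALSE)
  r <- abs(F_fa[valid]) / F_v[valid]
  list(max_fa_v_ratio = max(r),
       pct_above_slip = 100 * mean(r > mu),
       n_valid = sum(valid), n_excluded = sum(!valid))
}

# Peak semantics: the largest interior local maximum; if the channel has
# no interior peak inside the window, fall back to the window maximum and
# flag it.
.peak_max <- function(x) {
  n <- length(x)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    loc <- i[x[i] >= x[i - 1L] & x[i] >= x[i + 1L]]
    if (length(loc)) return(list(value = max(x[loc]), endpoint = FALSE))
  }
  list(value = max(x), endpoint = TRUE)
}

.signed_extremum <- function(x) x[which.max(abs(x))]

#' Compute the strike metric set
#'
#' Computes the 13 strike variables plus strike duration from
#' strike-frame smoothed signals and the detected window: maximum
#' fore--aft / lateral / vertical / total force (BW and N), maximum head
#' velocity and acceleration, fore--aft impulse, strike distance, maximum
#' tail velocity / acceleration / displacement along the strike axis
#' (signed extrema), maximum FA/V ratio, and the percentage of the strike
#' above the slip threshold. Force maxima use peak semantics (largest
#' interior local maximum of the smoothed channel, window max as a flagged
#' fallback).
#'
#' @param force_splines Named list of `smoothed_signal`s: `fa`, `lat`, `v`.
#' @param kin_splines Named list of `smoothed_signal`s: `head_fa`,
#'   `head_lat`, `tail_fa`, `tail_lat`.
#' @param events A [strike_events()].
#' @param meta A [trial_meta()].
#' @param fv_floor_bw Vertical-force validity floor for the slip ratio, in
#'   body weights (default 0.05).
#' @param tare Logical; subtract the pre-strike vertical baseline (mean
#'   vertical force over the 50 ms before onset) before reporting vertical
#'   and total maxima. Off by default: reported vertical maxima include
#'   resting body weight.
#' @param force_raw Optional strike-frame force trace (columns `time`,
#'   `fa`, `v`). When given, the slip ratio is computed from these raw
#'   samples rather than the smoothed channels: at the friction boundary
#'   (`|F_fa|/F_v` exactly at `mu`) spline jitter would otherwise flip
#'   boundary-equality samples above the threshold.
#' @return An object of class `strike_metrics` (named list with units in
#'   the field names).
#' @export
compute_metrics <- function(force_splines, kin_splines, events, meta,
                            fv_floor_bw = 0.05, tare = FALSE,
                            force_raw = NULL) {
  for (nm in c("fa", "lat", "v"))
    if (!inherits(force_splines[[nm]], "smoothed_signal"))
      stop("missing smoothed force channel: ", nm, call. = FALSE)
  for (nm in c("head_fa", "head_lat", "tail_fa", "tail_lat"))
    if (!inherits(kin_splines[[nm]], "smoothed_signal"))
      stop("missing smoothed kinematic channel: ", nm, call. = FALSE)
  bw <- meta$mass * meta$g
  dt <- 1 / meta$force_rate
  # evaluate on the recorded 1 kHz sample grid inside the window (off-grid
  # evaluation of a near-interpolating spline wiggles at sharp features)
  tw <- if (!is.null(force_raw))
    force_raw$time[force_raw$time >= events$t_onset &
                     force_raw$time <= events$t_end_forward]
  else seq(events$t_onset, events$t_end_forward, by = dt)
  if (length(tw) < 3L) stop("strike window too short", call. = FALSE)

  Ffa <- predict(force_splines$fa, tw)
  Flat <- predict(force_splines$lat, tw)
  Fv <- predict(force_splines$v, tw)
  baseline <- 0
  if (tare) {
    tb <- seq(max(force_splines$v$range[1], events$t_onset - 0.05),
              events$t_onset, by = dt)
    baseline <- mean(predict(force_splines$v, tb))
    Fv <- Fv - baseline
  }

  p_fa <- .peak_max(abs(Ffa)); p_lat <- .peak_max(abs(Flat))
  p_v <- .peak_max(Fv)
  p_tot <- .peak_max(sqrt(Ffa^2 + Flat^2 + Fv^2))
  endpoint_peaks <- c(fa = p_fa$endpoint, lat = p_lat$endpoint,
                      v = p_v$endpoint, total = p_tot$endpoint)

  vh_fa <- predict(kin_splines$head_fa, tw, deriv = 1L)
  vh_lat <- predict(kin_splines$head_lat, tw, deriv = 1L)
  ah_fa <- predict(kin_splines$head_fa, tw, deriv = 2L)
  ah_lat <- predict(kin_splines$head_lat, tw, deriv = 2L)
  p_speed <- .peak_max(sqrt(vh_fa^2 + vh_lat^2))
  p_accel <- .peak_max(sqrt(ah_fa^2 + ah_lat^2))

  h0 <- c(predict(kin_splines$head_fa, events$t_onset),
          predict(kin_splines$head_lat, events$t_onset))
  h1 <- c(predict(kin_splines$head_fa, events$t_end_forward),
          predict(kin_splines$head_lat, events$t_end_forward))
  distance <- sqrt(sum((h1 - h0)^2))

  s_t <- predict(kin_splines$tail_fa, tw) -
    predict(kin_splines$tail_fa, events$t_onset)
  v_t <- predict(kin_splines$tail_fa, tw, deriv = 1L)
  a_t <- predict(kin_splines$tail_fa, tw, deriv = 2L)

  if (!is.null(force_raw)) {
    sel <- force_raw$time >= events$t_onset & force_raw$time <= events$t_end_forward
    slip <- slip_fraction(force_raw$fa[sel], force_raw$v[sel] - baseline,
                          meta$mu, fv_floor = fv_floor_bw * bw)
  } else {
    slip <- slip_fraction(Ffa, Fv, meta$mu, fv_floor = fv_floor_bw * bw)
  }
  impulse <- fore_aft_impulse(tw, Ffa)

  structure(list(
    max_fa_force_bw = p_fa$value / bw, max_fa_force_n = p_fa$value,
    max_lateral_force_bw = p_lat$value / bw, max_lateral_force_n = p_lat$value,
    max_vertical_force_bw = p_v$value / bw, max_vertical_force_n = p_v$value,
    max_total_force_bw = p_tot$value / bw, max_total_force_n = p_tot$value,
    max_head_velocity = p_speed$value,
    max_head_acceleration = p_accel$value,
    fa_impulse_ns = impulse, fa_impulse_bws = impulse / bw,
    strike_distance = distance,
    max_tail_velocity = .signed_extremum(v_t),
    max_tail_acceleration = .signed_extremum(a_t),
    max_tail_displacement = .signed_extremum(s_t),
    max_fa_v_ratio = slip$max_fa_v_ratio,
    pct_above_slip = slip$pct_above_slip,
    strike_duration = events$duration,
    t_onset = events$t_onset, t_end_forward = events$t_end_forward,
    n_slip_valid = slip$n_valid, n_slip_excluded = slip$n_excluded,
    vertical_baseline = baseline, endpoint_peaks = endpoint_peaks
  ), class = "strike_metrics")
}

#' Analyze one strike trial
#'
#' The full per-trial pipeline: synchronize the force and video clocks,
#' detect a provisional onset from head speed, determine the strike
#' direction from the first `n_frames_dir` frames of head travel, rotate
#' forces and positions into the strike frame, smooth every channel with a
#' GCV spline, detect the strike window on the fore--aft head velocity,
#' and compute the strike metric set.
#'
#' @param force A [strike_force_trace()] (sensor frame) or a
#'   `strike_trial` list, in which case `kin` and `meta` are taken from it.
#' @param kin A [strike_kinematic_trace()] (camera frame).
#' @param meta A [trial_meta()].
#' @param spar Optional fixed smoothing parameter for all channels
#'   (default: per-channel GCV).
#' @param n_frames_dir Frames defining the strike direction (default 10).
#' @param fv_floor_bw,tare Passed to [compute_metrics()].
#' @param min_peak,frac,floor,hold Passed to the event detector
#'   ([detect_onset()]).
#' @return An object of class `strike_analysis` with elements `metrics`,
#'   `events`, `frame` (the [strike_frame_spec()]), `meta`, `splines`,
#'   `signals` (smoothed channels evaluated on the 1 kHz analysis grid)
#'   and `overlap`.
#' @export
analyze_strike <- function(force, kin = NULL, meta = NULL, spar = NULL,
                           n_frames_dir = 10L, fv_floor_bw = 0.05,
                           tare = FALSE, min_peak = 0.1, frac = 0.05,
                           floor = 0.05, hold = 0.010) {
  if (inherits(force, "strike_trial")) {
    trial <- force
    force <- trial$force; kin <- trial$kin; meta <- trial$meta
  }
  stopifnot(inherits(force, "strike_force_trace"),
            inherits(kin, "strike_kinematic_trace"),
            inherits(meta, "trial_meta"))
  sync <- synchronize_trial(force, kin, meta)
  force <- sync$force; kin <- sync$kin
  dt <- 1 / meta$force_rate
  tg <- seq(sync$overlap[1], sync$overlap[2], by = dt)

  # Two-pass strike direction. Head speed (a magnitude) has a positive
  # noise floor that biases onset detection early, which would shrink the
  # 10-frame direction window into the quiet segment. First take a
  # provisional direction from the large displacement around peak speed,
  # project the velocity onto it (signed, zero-mean noise), detect onset
  # on that projection, then apply the 10-frame direction rule at the
  # detected onset on the smoothed head path.
  sx <- fit_smoothing_spline(kin$time, kin$head_x, spar = spar)
  sy <- fit_smoothing_spline(kin$time, kin$head_y, spar = spar)
  vx <- predict(sx, tg, deriv = 1L)
  vy <- predict(sy, tg, deriv = 1L)
  speed0 <- sqrt(vx^2 + vy^2)
  if (max(speed0) < min_peak)
    stop(sprintf("no strike detected: peak head speed %.3f m/s is below %.3f m/s",
                 max(speed0), min_peak), call. = FALSE)
  t_pk0 <- tg[which.max(speed0)]
  w0 <- n_frames_dir / (2 * meta$video_rate)
  th0 <- atan2(predict(sy, min(t_pk0 + w0, max(tg))) -
                 predict(sy, max(t_pk0 - w0, min(tg))),
               predict(sx, min(t_pk0 + w0, max(tg))) -
                 predict(sx, max(t_pk0 - w0, min(tg))))
  v_proj <- vx * cos(th0) + vy * sin(th0)
  onset0 <- detect_onset(tg, v_proj, min_peak = min_peak, frac = frac,
                         floor = floor, hold = hold)

  kin_s <- kin
  kin_s$head_x <- predict(sx, kin$time)
  kin_s$head_y <- predict(sy, kin$time)
  frame <- compute_strike_direction(kin_s, onset0, n_frames = n_frames_dir)
  force_r <- rotate_to_strike_frame(force, frame)
  kin_r <- rotate_to_strike_frame(kin, frame)

  force_splines <- list(
    fa = fit_smoothing_spline(force_r$time, force_r$fa, spar = spar),
    lat = fit_smoothing_spline(force_r$time, force_r$lat, spar = spar),
    v = fit_smoothing_spline(force_r$time, force_r$v, spar = spar))
  kin_splines <- list(
    head_fa = fit_smoothing_spline(kin_r$time, kin_r$head_fa, spar = spar),
    head_lat = fit_smoothing_spline(kin_r$time, kin_r$head_lat, spar = spar),
    tail_fa = fit_smoothing_spline(kin_r$time, kin_r$tail_fa, spar = spar),
    tail_lat = fit_smoothing_spline(kin_r$time, kin_r$tail_lat, spar = spar))

  v_fa <- predict(kin_splines$head_fa, tg, deriv = 1L)
  events <- detect_strike_events(tg, v_fa, min_peak = min_peak, frac = frac,
                                 floor = floor, hold = hold)
  metrics <- compute_metrics(force_splines, kin_splines, events, meta,
                             fv_floor_bw = fv_floor_bw, tare = tare,
                             force_raw = force_r)

  signals <- data.frame(
    time = tg,
    fa = predict(force_splines$fa, tg),
    lat = predict(force_splines$lat, tg),
    v = predict(force_splines$v, tg),
    head_velocity_fa = v_fa,
    head_accel_fa = predict(kin_splines$head_fa, tg, deriv = 2L),
    tail_velocity_fa = predict(kin_splines$tail_fa, tg, deriv = 1L),
    tail_accel_fa = predict(kin_splines$tail_fa, tg, deriv = 2L))

  structure(list(metrics = metrics, events = events, frame = frame,
                 meta = meta, splines = c(force_splines, kin_splines),
                 signals = signals, overlap = sync$overlap),
            class = "strike_analysis")
}

#' @export
print.strike_analysis <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Strike analysis: trial %s, individual %s (%s setup)\n",
              x$meta$trial_id, x$meta$individual_id, x$meta$setup))
  cat(sprintf("  window %.3f-%.3f s (duration %.0f ms), strike direction %.2f rad\n",
              x$events$t_onset, x$events$t_end_forward,
              1000 * m$strike_duration, x$frame$theta))
  cat(sprintf("  peak forces: FA %.2f BW, lateral %.2f BW, vertical %.2f BW, total %.2f BW\n",
              m$max_fa_force_bw, m$max_lateral_force_bw,
              m$max_vertical_force_bw, m$max_total_force_bw))
  cat(sprintf("  head: peak speed %.2f m/s, peak accel %.1f m/s^2, distance %.3f m\n",
              m$max_head_velocity, m$max_head_acceleration, m$strike_distance))
  cat(sprintf("  slip: max FA/V %.2f, %.1f%% of strike above mu = %.2f\n",
              m$max_fa_v_ratio, m$pct_above_slip, x$meta$mu))
  invisible(x)
}

#' @export
coef.strike_analysis <- function(object, ...) {
  m <- object$metrics
  c(max_fa_force_bw = m$max_fa_force_bw,
    max_lateral_force_bw = m$max_lateral_force_bw,
    max_vertical_force_bw = m$max_vertical_force_bw,
    max_total_force_bw = m$max_total_force_bw,
    max_head_velocity = m$max_head_velocity,
    max_head_acceleration = m$max_head_acceleration,
    fa_impulse_ns = m$fa_impulse_ns,
    strike_distance = m$strike_distance,
    max_tail_velocity = m$max_tail_velocity,
    max_tail_acceleration = m$max_tail_acceleration,
    max_tail_displacement = m$max_tail_displacement,
    max_fa_v_ratio = m$max_fa_v_ratio,
    pct_above_slip = m$pct_above_slip,
    strike_duration = m$strike_duration)
}

#' @export
summary.strike_analysis <- function(object, ...) {
  out <- list(coefficients = coef(object), theta = object$frame$theta,
              events = object$events, meta = object$meta,
              endpoint_peaks = object$metrics$endpoint_peaks)
  class(out) <- "summary.strike_analysis"
  out
}

#' @export
print.summary.strike_analysis <- function(x, ...) {
  cat("Strike metrics (13 variables + duration):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("strike direction theta = %.3f rad; ", x$theta))
  print(x$events)
  if (any(x$endpoint_peaks))
    cat("note: window-endpoint fallback used for peaks:",
        paste(names(which(x$endpoint_peaks)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.strike_analysis <- function(x, ...) {
  cf <- coef(x)
  cbind(data.frame(individual = x$meta$individual_id, setup = x$meta$setup,
                   trial = x$meta$trial_id, theta = x$frame$theta,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(cf)))
}

#' Plot a strike analysis
#'
#' Three stacked panels on the analysis time base: fore--aft head and tail
#' velocity, fore--aft head acceleration, and the smoothed force channels
#' in body weights, with the strike window marked.
#'
#' @param x A `strike_analysis`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.strike_analysis <- function(x, ...) {
  s <- x$signals
  bw <- x$meta$mass * x$meta$g
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  win <- c(x$events$t_onset, x$events$t_end_forward)
  panel <- function(ys, cols, ylab, legend) {
    graphics::matplot(s$time, ys, type = "l", lty = 1, col = cols,
                      xlab = "time (s)", ylab = ylab, ...)
    graphics::abline(v = win, lty = 3, col = "grey40")
    graphics::legend("topright", legend = legend, col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  }
  panel(cbind(s$head_velocity_fa, s$tail_velocity_fa), c("black", "orange"),
        "fore-aft velocity (m/s)", c("head", "tail"))
  panel(cbind(s$head_accel_fa, s$tail_accel_fa), c("black", "orange"),
        "fore-aft acceleration (m/s^2)", c("head", "tail"))
  panel(cbind(s$fa, s$lat, s$v, sqrt(s$fa^2 + s$lat^2 + s$v^2)) / bw,
        c("red", "blue", "grey50", "purple"), "force (BW)",
        c("fore-aft", "lateral", "vertical", "total"))
  invisible(x)
}
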