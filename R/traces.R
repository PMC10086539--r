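#' Trial metadata
#'
#' Describes one strike trial: the animal, the platform setup, the sampling
#' rates of the two instruments, and the camera-trigger sample that ties the
#' force and video clocks together.
#'
#' @param individual_id Character label of the animal.
#' @param setup Platform setup, `"open"` (featureless plane) or `"walled"`
#'   (two adjacent vertical walls opposite the strike direction).
#' @param trial_id Character label of the trial.
#' @param mass Snake mass in kg. Forces are normalised by `mass * g` into
#'   body weights (BW).
#' @param svl Snout--vent length in cm (recorded, not used in computation).
#' @param mu Substrate coefficient of static friction (default 0.30).
#' @param force_rate Force sampling rate in Hz (default 1000).
#' @param video_rate Video frame rate in Hz (default 500).
#' @param trigger_force_sample 1-based index of the force sample at which the
#'   camera trigger fired; video frame 1 is aligned to this sample.
#' @param scale_m_per_px Digitisation scale, metres per pixel (default 1e-3).
#' @param g Gravitational acceleration in m s^-2 (default 9.81).
#' @return An object of class `trial_meta` (a named list).
#' @export
trial_meta <- function(individual_id = "I1", setup = c("open", "walled"),
                       trial_id = "T1", mass = 0.5863, svl = 76.1,
                       mu = 0.30, force_rate = 1000, video_rate = 500,
                       trigger_force_sample = 1L, scale_m_per_px = 0.001,
                       g = 9.81) {
  setup <- match.arg(setup)
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("`mass` must be a single positive number (kg)", call. = FALSE)
  if (!is.finite(mu) || mu <= 0)
    stop("`mu` must be a positive friction coefficient", call. = FALSE)
  if (!is.finite(force_rate) || force_rate <= 0 ||
      !is.finite(video_rate) || video_rate <= 0)
    stop("sampling rates must be positive", call. = FALSE)
  if (!is.finite(scale_m_per_px) || scale_m_per_px <= 0)
    stop("`scale_m_per_px` must be positive", call. = FALSE)
  trigger_force_sample <- as.integer(trigger_force_sample)
  if (is.na(trigger_force_sample) || trigger_force_sample < 1L)
    stop("`trigger_force_sample` must be a positive integer index", call. = FALSE)
  structure(list(individual_id = as.character(individual_id), setup = setup,
                 trial_id = as.character(trial_id), mass = mass, svl = svl,
                 mu = mu, force_rate = force_rate, video_rate = video_rate,
                 trigger_force_sample = trigger_force_sample,
                 scale_m_per_px = scale_m_per_px, g = g),
            class = "trial_meta")
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf("Strike trial %s, individual %s (%s setup)\n",
              x$trial_id, x$individual_id, x$setup))
  cat(sprintf("  mass %.3f kg, SVL %.1f cm, mu = %.2f\n", x$mass, x$svl, x$mu))
  cat(sprintf("  force %g Hz, video %g Hz, trigger at force sample %d\n",
              x$force_rate, x$video_rate, x$trigger_force_sample))
  invisible(x)
}

.check_uniform_time <- function(time, what) {
  if (length(time) < 2L) stop(what, ": need at least 2 samples", call. = FALSE)
  if (any(!is.finite(time)))
    stop(what, ": non-finite time at row ", which(!is.finite(time))[1L],
         call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0))
    stop(what, ": time not strictly increasing at row ", which(dt <= 0)[1L] + 1L,
         call. = FALSE)
  bad <- which(abs(dt - dt[1L]) > 1e-9)
  if (length(bad))
    stop(sprintf("%s: non-uniform time step between rows %d and %d (%.6g vs %.6g s)",
                 what, bad[1L], bad[1L] + 1L, dt[bad[1L]], dt[1L]), call. = FALSE)
  invisible(dt[1L])
}

#' Force trace container
#'
#' Uniformly sampled ground-reaction force record in the sensor frame.
#' `fx`/`fy` are the horizontal (in-plane) channels, `fz` the vertical
#' channel; torques, when present, are carried along but unused.
#'
#' @param time Time in seconds, strictly increasing uniform grid.
#' @param fx,fy,fz Force channels in newtons.
#' @param torques Optional data frame of torque channels (N m).
#' @return A data frame of class `strike_force_trace`.
#' @export
strike_force_trace <- function(time, fx, fy, fz, torques = NULL) {
  n <- length(time)
  if (length(fx) != n || length(fy) != n || length(fz) != n)
    stop("force channels must match the time vector length", call. = FALSE)
  .check_uniform_time(time, "force trace")
  for (nm in c("fx", "fy", "fz")) {
    v <- get(nm)
    if (any(!is.finite(v)))
      stop(sprintf("force trace: non-finite %s at row %d", nm,
                   which(!is.finite(v))[1L]), call. = FALSE)
  }
  out <- data.frame(time = time, fx = fx, fy = fy, fz = fz)
  if (!is.null(torques)) attr(out, "torques") <- torques
  class(out) <- c("strike_force_trace", "data.frame")
  out
}

#' Kinematic trace container
#'
#' Uniformly sampled planar head and tail positions (metres, camera frame).
#'
#' @param time Time in seconds, uniform grid at the video rate.
#' @param head_x,head_y,tail_x,tail_y Digitised positions in metres.
#' @param interpolated_frames Optional integer vector of frame indices whose
#'   positions were filled by interpolation across short digitisation gaps.
#' @return A data frame of class `strike_kinematic_trace`.
#' @export
strike_kinematic_trace <- function(time, head_x, head_y, tail_x, tail_y,
                                   interpolated_frames = integer()) {
  n <- length(time)
  cols <- list(head_x = head_x, head_y = head_y,
               tail_x = tail_x, tail_y = tail_y)
  if (any(vapply(cols, length, 1L) != n))
    stop("kinematic channels must match the time vector length", call. = FALSE)
  .check_uniform_time(time, "kinematic trace")
  for (nm in names(cols))
    if (any(!is.finite(cols[[nm]])))
      stop(sprintf("kinematic trace: non-finite %s at row %d", nm,
                   which(!is.finite(cols[[nm]]))[1L]), call. = FALSE)
  out <- data.frame(time = time, head_x = head_x, head_y = head_y,
                    tail_x = tail_x, tail_y = tail_y)
  attr(out, "interpolated_frames") <- as.integer(interpolated_frames)
  class(out) <- c("strike_kinematic_trace", "data.frame")
  out
}

#' Strike window events
#'
#' The analysis window: strike onset to the end of forward progress (the
#' first post-peak instant at which fore--aft head velocity returns to zero).
#'
#' @param t_onset Onset time in seconds.
#' @param t_end_forward End-of-forward-progress time in seconds.
#' @param end_warning Logical; `TRUE` when forward progress never ended
#'   within the record and the last sample was used.
#' @return An object of class `strike_events`.
#' @export
strike_events <- function(t_onset, t_end_forward, end_warning = FALSE) {
  if (!is.finite(t_onset) || !is.finite(t_end_forward))
    stop("event times must be finite", call. = FALSE)
  if (t_onset >= t_end_forward)
    stop("t_onset must precede t_end_forward", call. = FALSE)
  structure(list(t_onset = t_onset, t_end_forward = t_end_forward,
                 duration = t_end_forward - t_onset,
                 end_warning = isTRUE(end_warning)),
            class = "strike_events")
}

#' @export
print.strike_events <- function(x, ...) {
  cat(sprintf("Strike window: onset %.4f s, forward progress ends %.4f s (duration %.1f ms)%s\n",
              x$t_onset, x$t_end_forward, 1000 * x$duration,
              if (x$end_warning) " [end = last sample, no zero crossing]" else ""))
  invisible(x)
}
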