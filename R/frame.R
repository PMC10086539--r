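#' Strike-frame specification
#'
#' A planar rotation taking the lab/sensor axes into the strike-aligned
#' frame: the strike direction maps to +x' (fore--aft), its left-hand
#' normal to y' (lateral); the vertical channel is untouched. The rotation
#' is `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`.
#'
#' @param theta Angle from the original +x axis to the strike direction,
#'   radians, in (-pi, pi].
#' @param origin Head position at onset (length-2, metres); positions are
#'   rotated about this point, forces as free vectors.
#' @return An object of class `strike_frame_spec`.
#' @export
strike_frame_spec <- function(theta, origin = c(0, 0)) {
  if (!is.finite(theta) || theta <= -pi || theta > pi)
    stop("`theta` must be finite and in (-pi, pi]", call. = FALSE)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-2 position", call. = FALSE)
  structure(list(theta = theta, origin = as.numeric(origin)),
            class = "strike_frame_spec")
}

#' Determine the strike direction
#'
#' The strike direction is the overall direction of head travel over the
#' first `n_frames` video frames after onset: `theta = atan2(dy, dx)` of
#' the head displacement from the onset frame to frame onset + n_frames.
#'
#' @param kin A [strike_kinematic_trace()] (camera frame, metres).
#' @param t_onset Strike onset time, seconds (on the synchronized axis).
#' @param n_frames Number of frames defining the direction window
#'   (default 10).
#' @return A [strike_frame_spec()] with the onset head position as origin.
#' @export
compute_strike_direction <- function(kin, t_onset, n_frames = 10L) {
  stopifnot(inherits(kin, "strike_kinematic_trace"))
  i0 <- which.min(abs(kin$time - t_onset))
  i1 <- i0 + as.integer(n_frames)
  if (i1 > nrow(kin))
    stop(sprintf("need %d frames after onset but only %d remain", n_frames,
                 nrow(kin) - i0), call. = FALSE)
  dx <- kin$head_x[i1] - kin$head_x[i0]
  dy <- kin$head_y[i1] - kin$head_y[i0]
  if (dx == 0 && dy == 0)
    stop("zero head displacement over the direction window: strike direction undefined",
         call. = FALSE)
  strike_frame_spec(atan2(dy, dx),
                    origin = c(kin$head_x[i0], kin$head_y[i0]))
}

.rot_mat <- function(theta)
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)

#' Rotate a trace into the strike frame
#'
#' Applies the planar rotation of `spec` to every sample. Forces rotate as
#' free vectors (`fx`,`fy` -> `fa`,`lat`; `fz` passes through as `v`).
#' Positions rotate about `spec$origin` (`head_x`,`head_y` ->
#' `head_fa`,`head_lat`, likewise for the tail).
#'
#' @param trace A [strike_force_trace()] or [strike_kinematic_trace()].
#' @param spec A [strike_frame_spec()].
#' @return A data frame in strike-frame coordinates, same class tag with
#'   `attr(, "frame") = "strike"`.
#' @export
rotate_to_strike_frame <- function(trace, spec) {
  stopifnot(inherits(spec, "strike_frame_spec"))
  ct <- cos(spec$theta); st <- sin(spec$theta)
  if (inherits(trace, "strike_force_trace")) {
    out <- data.frame(time = trace$time,
                      fa = trace$fx * ct + trace$fy * st,
                      lat = -trace$fx * st + trace$fy * ct,
                      v = trace$fz)
    class(out) <- c("strike_force_trace", "data.frame")
  } else if (inherits(trace, "strike_kinematic_trace")) {
    rot <- function(x, y) {
      x0 <- x - spec$origin[1]; y0 <- y - spec$origin[2]
      list(fa = x0 * ct + y0 * st, lat = -x0 * st + y0 * ct)
    }
    h <- rot(trace$head_x, trace$head_y)
    tl <- rot(trace$tail_x, trace$tail_y)
    out <- data.frame(time = trace$time, head_fa = h$fa, head_lat = h$lat,
                      tail_fa = tl$fa, tail_lat = tl$lat)
    class(out) <- c("strike_kinematic_trace", "data.frame")
  } else stop("unsupported trace type", call. = FALSE)
  attr(out, "frame") <- "strike"
  attr(out, "theta") <- spec$theta
  out
}
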