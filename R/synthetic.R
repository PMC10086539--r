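# Minimum-jerk quintic x(tau) = D (10 tau^3 - 15 tau^4 + 6 tau^5) and its
# analytic derivatives. Closed forms give exact oracles: peak speed
# 1.875 D/T at tau = 1/2, peak acceleration (10/sqrt(3)) D/T^2 at
# tau = 1/2 - 1/(2 sqrt(3)).

.mj_pos <- function(tau, D) D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
.mj_vel <- function(tau, D, T) (D / T) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
.mj_acc <- function(tau, D, T) (D / T^2) * (60 * tau - 180 * tau^2 + 120 * tau^3)

.mj_peak_speed <- function(D, T) 1.875 * D / T
.mj_peak_accel <- function(D, T) (10 / sqrt(3)) * D / T^2

# Evaluate expr with a temporary RNG state seeded at `seed`.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic strike scenario
#'
#' Parameters of one simulated defensive strike. The head follows a
#' minimum-jerk path of length `D` over duration `T`; the remaining body
#' mass acts as a second point mass whose recoil, in the open setup, is
#' chosen so the horizontal-to-vertical force ratio never exceeds the
#' substrate friction coefficient (the Coulomb no-slip condition).
#'
#' Defaults reproduce the study conditions of the experiments the package
#' targets: strike distance 0.21 m, snake mass 0.5863 kg, friction
#' coefficient 0.30, 1 kHz force sampling and 500 Hz video. The default
#' duration 0.12 s is chosen so the minimum-jerk peak head speed
#' (1.875 D/T = 3.28 m s^-1) matches the reported mean peak speed; see the
#' methods vignette.
#'
#' @param D Strike distance in metres (> 0, or 0 for a stationary control).
#' @param T Strike duration in seconds.
#' @param azimuth Direction of head travel in the lab frame, radians.
#' @param head_mass_fraction Fraction of total mass assigned to the moving
#'   head/anterior-body point mass, in (0, 1].
#' @param mass Total snake mass in kg.
#' @param mu Substrate friction coefficient.
#' @param setup `"open"` (friction-capped, tail recoils) or `"walled"`
#'   (tail braced, no cap).
#' @param noise_sd_force Gaussian noise SD added to each force channel (N).
#' @param noise_sd_position Gaussian noise SD added to each digitised
#'   coordinate (m).
#' @param seed Integer seed controlling the noise draws.
#' @param g Gravitational acceleration, m s^-2.
#' @param force_rate,video_rate Sampling rates in Hz; `force_rate` must be
#'   an integer multiple of `video_rate`.
#' @param lead_in,lead_out Quiet padding before/after the strike, seconds.
#' @param v_bump_bw Peak of the smooth vertical-force bump added on top of
#'   body weight during the strike, in body weights (default 0.5, so
#'   vertical maxima reach about 1.5 BW as in recorded strikes).
#' @param max_tail_accel Plausibility bound on tail acceleration magnitude
#'   (m s^-2); an open-setup scenario needing more recoil than this is
#'   rejected as infeasible.
#' @param cap_margin Fractional safety margin of the open-setup friction
#'   cap: tail recoil holds the force ratio at `(1 - cap_margin) * mu`
#'   ("at or just below" the friction coefficient). With a margin of zero
#'   half the capped samples would sit above `mu` after any symmetric
#'   sensor noise; the default 0.02 keeps the noiseless ratio strictly
#'   below the slip threshold.
#' @param head_start Head position at strike onset in the camera frame (m).
#' @param tail_offset Distance of the tail point behind the head at onset (m).
#' @return An object of class `strike_scenario`.
#' @export
strike_scenario <- function(D = 0.21, T = 0.12, azimuth = 0,
                            head_mass_fraction = 0.3, mass = 0.5863,
                            mu = 0.30, setup = c("open", "walled"),
                            noise_sd_force = 0.02, noise_sd_position = 0.001,
                            seed = 1L, g = 9.81,
                            force_rate = 1000, video_rate = 500,
                            lead_in = 0.15, lead_out = 0.15,
                            v_bump_bw = 0.5, max_tail_accel = 500,
                            cap_margin = 0.02,
                            head_start = c(0, 0), tail_offset = 0.4) {
  setup <- match.arg(setup)
  if (!is.finite(D) || D < 0) stop("`D` must be >= 0", call. = FALSE)
  if (!is.finite(T) || T <= 0) stop("`T` must be > 0", call. = FALSE)
  if (!is.finite(head_mass_fraction) || head_mass_fraction <= 0 ||
      head_mass_fraction > 1)
    stop("`head_mass_fraction` must be in (0, 1]", call. = FALSE)
  if (!is.finite(mass) || mass <= 0) stop("`mass` must be > 0", call. = FALSE)
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (noise_sd_force < 0 || noise_sd_position < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (!is.finite(cap_margin) || cap_margin < 0 || cap_margin >= 1)
    stop("`cap_margin` must be in [0, 1)", call. = FALSE)
  if (force_rate %% video_rate != 0)
    stop("`force_rate` must be an integer multiple of `video_rate`",
         call. = FALSE)
  structure(list(D = D, T = T, azimuth = azimuth,
                 head_mass_fraction = head_mass_fraction, mass = mass,
                 mu = mu, setup = setup, noise_sd_force = noise_sd_force,
                 noise_sd_position = noise_sd_position,
                 seed = as.integer(seed), g = g, force_rate = force_rate,
                 video_rate = video_rate, lead_in = lead_in,
                 lead_out = lead_out, v_bump_bw = v_bump_bw,
                 max_tail_accel = max_tail_accel, cap_margin = cap_margin,
                 head_start = head_start,
                 tail_offset = tail_offset),
            class = "strike_scenario")
}

# Shared simulation engine: noiseless dynamics on the 1 kHz force grid.
# Returns sample series, the truth record, and grid bookkeeping.
.simulate_strike <- function(sc) {
  if (sc$T < 4 / sc$video_rate)
    stop(sprintf("strike duration %.4f s is shorter than 4 video frames (%.4f s); window too short to analyze",
                 sc$T, 4 / sc$video_rate), call. = FALSE)
  dt <- 1 / sc$force_rate
  t0 <- sc$lead_in
  t_total <- sc$lead_in + sc$T + sc$lead_out
  time <- seq(0, t_total, by = dt)
  tau <- pmin(pmax((time - t0) / sc$T, 0), 1)
  in_win <- time >= t0 & time <= t0 + sc$T

  m_h <- sc$head_mass_fraction * sc$mass
  m_t <- sc$mass - m_h

  x_h <- .mj_pos(tau, sc$D)                       # along-strike head coordinate
  a_h <- ifelse(in_win, .mj_acc(tau, sc$D, sc$T), 0)

  # vertical force: body weight plus a smooth half-sine bump during the strike
  bw <- sc$mass * sc$g
  F_v <- bw + ifelse(in_win, sc$v_bump_bw * bw * sin(pi * tau), 0)

  F_req <- m_h * a_h
  if (sc$setup == "walled" || m_t == 0) {
    F_fa <- F_req
    a_t <- rep(0, length(time))
  } else {
    cap <- (1 - sc$cap_margin) * sc$mu * F_v
    # C1-smooth saturation instead of a hard clamp: h(u) = u below 0.6,
    # quadratic blend to 1 by u = 1.4. Corner-free tail accelerations are
    # both more physiological and recoverable by spline differentiation.
    u <- abs(F_req) / cap
    blend <- 0.6
    h <- ifelse(u <= blend, u,
                ifelse(u >= 2 - blend, 1,
                       u - (u - blend)^2 / (4 * (1 - blend))))
    F_fa <- sign(F_req) * cap * h
    a_t <- (F_fa - F_req) / m_t
    if (any(abs(a_t) > sc$max_tail_accel)) {
      i <- which.max(abs(a_t))
      stop(sprintf("open-setup scenario infeasible: required tail acceleration %.1f m s^-2 exceeds the plausibility bound %.1f at sample %d (t = %.4f s)",
                   abs(a_t[i]), sc$max_tail_accel, i, time[i]), call. = FALSE)
    }
  }

  # velocities by cumulative trapezoid so the impulse-momentum identity
  # holds exactly on the sample grid
  v_h <- as.numeric(pracma::cumtrapz(time, a_h))
  v_t <- as.numeric(pracma::cumtrapz(time, a_t))
  s_t <- as.numeric(pracma::cumtrapz(time, v_t))   # signed tail displacement

  dir <- c(cos(sc$azimuth), sin(sc$azimuth))
  head_x <- sc$head_start[1] + dir[1] * x_h
  head_y <- sc$head_start[2] + dir[2] * x_h
  tail_x <- sc$head_start[1] - dir[1] * sc$tail_offset + dir[1] * s_t
  tail_y <- sc$head_start[2] - dir[2] * sc$tail_offset + dir[2] * s_t

  ratio <- abs(F_fa) / F_v
  win <- which(in_win)
  impulse <- pracma::trapz(time[win], F_fa[win])

  ext_signed <- function(x) x[which.max(abs(x))]
  truth <- list(
    peak_head_speed = .mj_peak_speed(sc$D, sc$T),
    peak_head_accel = .mj_peak_accel(sc$D, sc$T),
    strike_distance = sc$D,
    strike_duration = sc$T,
    max_fa_force_bw = max(abs(F_fa)) / bw,
    max_lateral_force_bw = 0,
    max_vertical_force_bw = max(F_v) / bw,
    max_total_force_bw = max(sqrt(F_fa^2 + F_v^2)) / bw,
    fa_impulse_ns = impulse,
    max_fa_v_ratio = max(ratio[win]),
    pct_above_slip = 100 * mean(ratio[win] > sc$mu),
    max_tail_displacement = ext_signed(s_t),
    max_tail_velocity = ext_signed(v_t),
    max_tail_acceleration = ext_signed(a_t),
    head_mass = m_h, tail_mass = m_t,
    t_onset = t0, t_end_forward = t0 + sc$T
  )
  stopifnot(all(vapply(truth, is.finite, TRUE)))

  list(time = time, in_win = in_win, a_h = a_h, v_h = v_h,
       a_t = a_t, v_t = v_t, s_t = s_t, F_fa = F_fa, F_v = F_v,
       head_x = head_x, head_y = head_y, tail_x = tail_x, tail_y = tail_y,
       dir = dir, truth = truth)
}

.kin_from_sim <- function(sc, sim) {
  step <- as.integer(sc$force_rate / sc$video_rate)
  idx <- seq(1L, length(sim$time), by = step)
  kin <- strike_kinematic_trace(sim$time[idx],
                                sim$head_x[idx], sim$head_y[idx],
                                sim$tail_x[idx], sim$tail_y[idx])
  if (sc$noise_sd_position > 0) {
    n <- nrow(kin)
    for (col in c("head_x", "head_y", "tail_x", "tail_y"))
      kin[[col]] <- kin[[col]] + stats::rnorm(n, 0, sc$noise_sd_position)
  }
  kin
}

#' Generate a minimum-jerk strike (kinematics only)
#'
#' Samples head and tail positions of a simulated strike at the video rate
#' and returns them with the analytic ground truth (peak speed
#' `1.875 D/T`, peak acceleration `(10/sqrt(3)) D/T^2`, distance, duration).
#'
#' @param scenario A [strike_scenario()].
#' @return A list with elements `kin` (a [strike_kinematic_trace()]) and
#'   `truth` (named list of ground-truth values).
#' @export
generate_min_jerk_strike <- function(scenario) {
  stopifnot(inherits(scenario, "strike_scenario"))
  sim <- .simulate_strike(scenario)
  kin <- .with_seed(scenario$seed, .kin_from_sim(scenario, sim))
  list(kin = kin, truth = sim$truth)
}

#' Generate a full two-mass strike trial
#'
#' Simulates a strike under two-point-mass Newtonian dynamics: the head
#' mass follows a minimum-jerk path; the horizontal ground reaction force
#' is `m_h a_h + m_t a_t`; the vertical force is body weight plus a smooth
#' bump. In the open setup the tail point mass recoils rearward exactly as
#' much as needed to keep `|F_fa|/F_v <= mu` at every sample (the inertial
#' appendage mechanism); in the walled setup the tail is braced and no cap
#' applies. Gaussian sensor/digitisation noise is then added under the
#' scenario seed.
#'
#' @param scenario A [strike_scenario()].
#' @return An object of class `strike_trial`: a list with `force`
#'   (a [strike_force_trace()] at the force rate), `kin`
#'   (a [strike_kinematic_trace()] at the video rate), `meta`
#'   (a [trial_meta()]), `truth` (ground-truth record from the noiseless
#'   signals), and `series` (the noiseless per-sample dynamics, for
#'   momentum bookkeeping checks).
#' @export
generate_two_mass_trial <- function(scenario) {
  stopifnot(inherits(scenario, "strike_scenario"))
  sc <- scenario
  sim <- .simulate_strike(sc)
  dir <- sim$dir

  fx <- sim$F_fa * dir[1]
  fy <- sim$F_fa * dir[2]
  fz <- sim$F_v
  out <- .with_seed(sc$seed, {
    if (sc$noise_sd_force > 0) {
      n <- length(fx)
      fx <- fx + stats::rnorm(n, 0, sc$noise_sd_force)
      fy <- fy + stats::rnorm(n, 0, sc$noise_sd_force)
      fz <- fz + stats::rnorm(n, 0, sc$noise_sd_force)
    }
    force <- strike_force_trace(sim$time, fx, fy, fz)
    kin <- .kin_from_sim(sc, sim)
    list(force = force, kin = kin)
  })

  meta <- trial_meta(individual_id = "SYN", setup = sc$setup,
                     trial_id = sprintf("syn-%d", sc$seed), mass = sc$mass,
                     svl = NA_real_, mu = sc$mu, force_rate = sc$force_rate,
                     video_rate = sc$video_rate, trigger_force_sample = 1L,
                     g = sc$g)
  series <- data.frame(time = sim$time, a_h = sim$a_h, v_h = sim$v_h,
                       a_t = sim$a_t, v_t = sim$v_t, s_t = sim$s_t,
                       F_fa = sim$F_fa, F_v = sim$F_v)
  structure(list(force = out$force, kin = out$kin, meta = meta,
                 truth = sim$truth, series = series, scenario = sc),
            class = "strike_trial")
}

#' @export
print.strike_trial <- function(x, ...) {
  cat(sprintf("Synthetic strike trial (%s setup): %d force samples @ %g Hz, %d frames @ %g Hz\n",
              x$meta$setup, nrow(x$force), x$meta$force_rate,
              nrow(x$kin), x$meta$video_rate))
  cat(sprintf("  truth: D = %.3f m, T = %.0f ms, peak speed %.2f m/s, peak accel %.1f m/s^2\n",
              x$truth$strike_distance, 1000 * x$truth$strike_duration,
              x$truth$peak_head_speed, x$truth$peak_head_accel))
  invisible(x)
}

#' Closed-form force profile
#'
#' A named analytic force profile used by the direct-profile generator,
#' where calibration values (peak forces, impulses, slip fractions) are set
#' by construction rather than emerging from dynamics.
#'
#' @param shape One of `"half_sine"`, `"trapezoid"`, `"constant"`,
#'   `"piecewise"`, `"zero"`.
#' @param amplitude Peak amplitude above baseline, newtons.
#' @param onset Support start time, seconds.
#' @param duration Support length, seconds.
#' @param baseline Value outside (and, additively, inside) the support, N.
#' @param plateau_frac For `"trapezoid"`: fraction of the support at full
#'   amplitude (symmetric linear ramps on either side).
#' @param breaks,values For `"piecewise"`: breakpoints (length `k + 1`,
#'   within the support) and the constant value on each of the `k`
#'   half-open intervals `[breaks[i], breaks[i+1])`.
#' @return An object of class `force_profile` with `$eval(t)` and a
#'   closed-form `$impulse(a, b)` over any interval.
#' @export
force_profile <- function(shape = c("half_sine", "trapezoid", "constant",
                                    "piecewise", "zero"),
                          amplitude = 0, onset = 0, duration = 0.1,
                          baseline = 0, plateau_frac = 0.5,
                          breaks = NULL, values = NULL) {
  shape <- match.arg(shape)
  if (shape != "zero" && (!is.finite(onset) || !is.finite(duration) || duration <= 0))
    stop("profile support must have positive duration", call. = FALSE)
  if (shape == "piecewise") {
    if (is.null(breaks) || is.null(values) || length(breaks) != length(values) + 1L)
      stop("piecewise profile needs `breaks` (k+1) and `values` (k)", call. = FALSE)
    if (is.unsorted(breaks, strictly = TRUE))
      stop("piecewise `breaks` must be strictly increasing", call. = FALSE)
    onset <- breaks[1L]
    duration <- breaks[length(breaks)] - breaks[1L]
  }
  end <- onset + duration
  ev <- switch(shape,
    zero = function(t) rep(0, length(t)),
    half_sine = function(t) {
      inside <- t >= onset & t <= end
      baseline + ifelse(inside, amplitude * sin(pi * (t - onset) / duration), 0)
    },
    constant = function(t) {
      inside <- t >= onset & t < end
      baseline + ifelse(inside, amplitude, 0)
    },
    trapezoid = function(t) {
      ramp <- duration * (1 - plateau_frac) / 2
      u <- t - onset
      inside <- u >= 0 & u <= duration
      shapev <- pmin(pmin(u / ramp, 1), (duration - u) / ramp)
      baseline + ifelse(inside, amplitude * pmax(shapev, 0), 0)
    },
    piecewise = function(t) {
      out <- rep(baseline, length(t))
      for (i in seq_along(values)) {
        inside <- t >= breaks[i] & t < breaks[i + 1L]
        out[inside] <- out[inside] + values[i]
      }
      out
    })
  imp <- function(a, b) {
    base_part <- baseline * (b - a)
    lo <- max(a, onset); hi <- min(b, end)
    if (shape == "zero") return(0)
    if (lo >= hi) return(base_part)
    extra <- switch(shape,
      half_sine = amplitude * duration / pi *
        (cos(pi * (lo - onset) / duration) - cos(pi * (hi - onset) / duration)),
      constant = amplitude * (hi - lo),
      trapezoid = {
        # integrate the unit trapezoid numerically-exactly via its vertices
        ramp <- duration * (1 - plateau_frac) / 2
        verts <- c(onset, onset + ramp, end - ramp, end)
        vals <- c(0, 1, 1, 0)
        xs <- sort(unique(pmin(pmax(verts, lo), hi)))
        xs <- unique(c(lo, xs, hi))
        ys <- stats::approx(verts, vals, xs, rule = 2)$y
        amplitude * pracma::trapz(xs, ys)
      },
      piecewise = {
        s <- 0
        for (i in seq_along(values)) {
          l2 <- max(lo, breaks[i]); h2 <- min(hi, breaks[i + 1L])
          if (h2 > l2) s <- s + values[i] * (h2 - l2)
        }
        s
      })
    base_part + extra
  }
  structure(list(shape = shape, amplitude = amplitude, onset = onset,
                 duration = duration, baseline = baseline,
                 plateau_frac = plateau_frac, breaks = breaks,
                 values = values, eval = ev, impulse = imp),
            class = "force_profile")
}

#' Generate a direct-profile calibration trial
#'
#' Builds a trial whose force channels follow stated closed-form profiles
#' inside a stated strike window, paired with a minimum-jerk head motion
#' spanning the same window so that event detection works. Calibration
#' targets (force maxima, impulse, slip fraction) are known exactly from
#' the profile definitions.
#'
#' @param fa,lateral,vertical [force_profile()]s for the strike-aligned
#'   fore--aft, lateral, and vertical channels (newtons; `vertical` should
#'   normally carry body weight as its baseline).
#' @param window Numeric length-2: strike window (onset, end) in seconds.
#' @param meta A [trial_meta()].
#' @param t_total Total record length in seconds (default: window end plus
#'   the window onset as symmetric padding).
#' @param kin_D Head travel distance of the accompanying minimum-jerk
#'   kinematics, metres.
#' @return A `strike_trial` list: `force`, `kin`, `meta`, `truth`.
#' @export
generate_direct_profile_trial <- function(fa, lateral = force_profile("zero"),
                                          vertical, window, meta,
                                          t_total = NULL, kin_D = 0.21) {
  stopifnot(inherits(fa, "force_profile"), inherits(lateral, "force_profile"),
            inherits(vertical, "force_profile"), inherits(meta, "trial_meta"))
  if (length(window) != 2L || window[1] >= window[2])
    stop("`window` must be (onset, end) with onset < end", call. = FALSE)
  if (is.null(t_total)) t_total <- window[2] + window[1]
  for (p in list(fa, lateral, vertical))
    if (p$shape != "zero" &&
        (p$onset < 0 || p$onset + p$duration > t_total + 1e-12))
      stop(sprintf("profile support [%.4f, %.4f] lies outside the record [0, %.4f]",
                   p$onset, p$onset + p$duration, t_total), call. = FALSE)

  dt <- 1 / meta$force_rate
  time <- seq(0, t_total, by = dt)
  Ffa <- fa$eval(time); Flat <- lateral$eval(time); Fv <- vertical$eval(time)
  force <- strike_force_trace(time, Ffa, Flat, Fv)

  kin_sc <- strike_scenario(D = kin_D, T = window[2] - window[1], azimuth = 0,
                            mass = meta$mass, mu = meta$mu, setup = meta$setup,
                            noise_sd_force = 0, noise_sd_position = 0,
                            force_rate = meta$force_rate,
                            video_rate = meta$video_rate,
                            lead_in = window[1], lead_out = t_total - window[2])
  kin <- generate_min_jerk_strike(kin_sc)$kin

  bw <- meta$mass * meta$g
  win <- time >= window[1] & time <= window[2]
  ratio <- abs(Ffa[win]) / Fv[win]
  valid <- Fv[win] >= 0.05 * bw
  truth <- list(
    max_fa_force_bw = (abs(fa$baseline) + fa$amplitude) / bw,
    max_lateral_force_bw = (abs(lateral$baseline) + lateral$amplitude) / bw,
    max_vertical_force_bw = (vertical$baseline + vertical$amplitude) / bw,
    max_total_force_bw = max(sqrt(Ffa[win]^2 + Flat[win]^2 + Fv[win]^2)) / bw,
    fa_impulse_ns = fa$impulse(window[1], window[2]),
    max_fa_v_ratio = if (any(valid)) max(ratio[valid]) else NA_real_,
    pct_above_slip = if (any(valid)) 100 * mean(ratio[valid] > meta$mu) else NA_real_,
    strike_distance = kin_D,
    strike_duration = window[2] - window[1],
    t_onset = window[1], t_end_forward = window[2]
  )
  structure(list(force = force, kin = kin, meta = meta, truth = truth),
            class = "strike_trial")
}

#' Generate a cohort of per-trial metric values
#'
#' Draws per-trial values of one or more strike variables from the additive
#' mixed model `grand mean + setup effect + individual effect +
#' setup x individual effect + residual`, with the individual and
#' interaction terms drawn once per level and the residual per trial. This
#' is the null/effect model under which the statistical layer is
#' calibrated.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param trials_per_setup Trials per individual per setup (>= 2).
#' @param grand_mean Named numeric vector: grand mean per variable.
#' @param setup_effect Named numeric vector, same names: the open-minus-
#'   walled difference per variable (applied as +/- half to each setup).
#' @param between_individual_sd,interaction_sd,residual_sd SDs of the
#'   random terms (scalars or named vectors; must be >= 0).
#' @param seed Integer seed.
#' @return A data frame with columns `individual`, `setup`, `trial` and one
#'   column per variable; the realised effects are attached as
#'   `attr(, "truth")`.
#' @export
generate_cohort <- function(n_individuals = 4, trials_per_setup = 6,
                            grand_mean = c(value = 0),
                            setup_effect = c(value = 0),
                            between_individual_sd = 1, interaction_sd = 1,
                            residual_sd = 1, seed = 1L) {
  if (n_individuals < 2) stop("need >= 2 individuals", call. = FALSE)
  if (trials_per_setup < 2) stop("need >= 2 trials per setup", call. = FALSE)
  vars <- names(grand_mean)
  if (is.null(vars)) { vars <- "value"; names(grand_mean) <- vars }
  expand1 <- function(x, what) {
    if (is.null(names(x))) x <- stats::setNames(rep(x, length.out = length(vars)), vars)
    if (any(x < 0)) stop(what, " must be >= 0", call. = FALSE)
    x[vars]
  }
  setup_effect <- {
    se <- setup_effect
    if (is.null(names(se))) se <- stats::setNames(rep(se, length.out = length(vars)), vars)
    se[vars]
  }
  isd <- expand1(between_individual_sd, "between_individual_sd")
  xsd <- expand1(interaction_sd, "interaction_sd")
  rsd <- expand1(residual_sd, "residual_sd")

  setups <- c("open", "walled")
  grid <- expand.grid(trial = seq_len(trials_per_setup), setup = setups,
                      individual = sprintf("I%d", seq_len(n_individuals)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("individual", "setup", "trial")]

  .with_seed(seed, {
    truth <- list()
    for (v in vars) {
      b_ind <- stats::rnorm(n_individuals, 0, isd[[v]])
      b_int <- matrix(stats::rnorm(2 * n_individuals, 0, xsd[[v]]),
                      nrow = n_individuals, ncol = 2,
                      dimnames = list(NULL, setups))
      ind_idx <- as.integer(factor(grid$individual,
                                   levels = sprintf("I%d", seq_len(n_individuals))))
      set_idx <- ifelse(grid$setup == "open", 1L, 2L)
      fixed <- grand_mean[[v]] +
        ifelse(grid$setup == "open", 0.5, -0.5) * setup_effect[[v]]
      grid[[v]] <- fixed + b_ind[ind_idx] +
        b_int[cbind(ind_idx, set_idx)] +
        stats::rnorm(nrow(grid), 0, rsd[[v]])
      truth[[v]] <- list(grand_mean = grand_mean[[v]],
                         setup_effect = setup_effect[[v]],
                         individual_effects = b_ind,
                         interaction_effects = b_int)
    }
    attr(grid, "truth") <- truth
    grid
  })
}
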