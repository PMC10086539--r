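test_that("body-weight normalisation divides by mass times gravity", {
  expect_equal(to_body_weights(9.81, 1.0), 1.0)
  expect_equal(to_body_weights(0, 2), 0)
  expect_equal(to_body_weights(5.0, 0.58), 5.0 / (0.58 * 9.81),
               tolerance = 1e-12)
  expect_error(to_body_weights(1, 0), "positive")
})

test_that("fore-aft impulse is a windowed trapezoidal integral", {
  tt <- seq(0, 0.3, by = 1e-3)
  ev <- strike_events(0.1, 0.2)
  expect_equal(fore_aft_impulse(tt, rep(1, length(tt)), ev), 0.1,
               tolerance = 1e-9)
  # half-sine closed form 2 F0 T / pi
  f <- ifelse(tt >= 0.1 & tt <= 0.2, sin(pi * (tt - 0.1) / 0.1), 0)
  expect_equal(fore_aft_impulse(tt, f, ev), 2 * 0.1 / pi, tolerance = 1e-4)
  # odd symmetry integrates to zero
  g <- ifelse(tt >= 0.1 & tt <= 0.2, sin(2 * pi * (tt - 0.1) / 0.1), 0)
  expect_lt(abs(fore_aft_impulse(tt, g, ev)), 1e-9)
  # additivity over adjacent windows
  set.seed(3)
  h <- stats::rnorm(length(tt))
  i1 <- fore_aft_impulse(tt, h, strike_events(0.05, 0.15))
  i2 <- fore_aft_impulse(tt, h, strike_events(0.15, 0.25))
  i3 <- fore_aft_impulse(tt, h, strike_events(0.05, 0.25))
  expect_equal(i1 + i2, i3, tolerance = 1e-9)
  expect_error(fore_aft_impulse(tt, h, strike_events(0.4, 0.5)), "empty")
})

test_that("slip statistic counts samples above the friction ratio", {
  n <- 100
  Fv <- rep(10, n)
  expect_equal(slip_fraction(rep(2, n), Fv, 0.3)$pct_above_slip, 0)
  expect_equal(slip_fraction(rep(2, n), Fv, 0.3)$max_fa_v_ratio, 0.2)
  expect_equal(slip_fraction(rep(5, n), Fv, 0.3)$pct_above_slip, 100)
  r <- c(rep(5, 25), rep(2, 75))
  out <- slip_fraction(r, Fv, 0.3)
  expect_equal(out$pct_above_slip, 25)
  expect_equal(out$max_fa_v_ratio, 0.5)
  # low vertical load is excluded, not counted
  Fv2 <- c(rep(10, 50), rep(0.01, 50))
  out2 <- slip_fraction(r, Fv2, 0.3, fv_floor = 1)
  expect_equal(out2$n_excluded, 50)
  expect_equal(out2$pct_above_slip, 50)  # 25 of 50 valid
  expect_error(slip_fraction(r, rep(0, n), 0.3, fv_floor = 1), "excluded")
})

test_that("direct-profile calibration trials are recovered within 2 percent", {
  tr <- half_sine_trial(fa_bw = 0.64, v_extra_bw = 0.5)
  a <- analyze_strike(tr)
  m <- a$metrics; tt <- tr$truth
  expect_equal(m$max_fa_force_bw, tt$max_fa_force_bw, tolerance = 0.02)
  expect_equal(m$max_vertical_force_bw, tt$max_vertical_force_bw,
               tolerance = 0.02)
  expect_equal(m$max_total_force_bw, tt$max_total_force_bw, tolerance = 0.02)
  expect_equal(m$fa_impulse_ns, tt$fa_impulse_ns, tolerance = 0.02)
  expect_equal(m$max_fa_v_ratio, tt$max_fa_v_ratio, tolerance = 0.02)
  expect_equal(m$strike_distance, tt$strike_distance, tolerance = 0.02)
})

test_that("noiseless two-mass trials recover every truth field", {
  for (setup in c("open", "walled")) {
    tr <- generate_two_mass_trial(noiseless_scenario(setup = setup))
    a <- analyze_strike(tr)
    m <- a$metrics; tt <- tr$truth
    rel <- function(x, y) abs(x - y) / max(abs(y), 1e-6)
    expect_lt(rel(m$max_head_velocity, tt$peak_head_speed), 0.02)
    expect_lt(rel(m$max_head_acceleration, tt$peak_head_accel), 0.05)
    expect_lt(rel(m$strike_distance, tt$strike_distance), 0.02)
    expect_lt(rel(m$max_fa_force_bw, tt$max_fa_force_bw), 0.02)
    expect_lt(rel(m$max_vertical_force_bw, tt$max_vertical_force_bw), 0.02)
    expect_lt(rel(m$max_total_force_bw, tt$max_total_force_bw), 0.02)
    expect_lt(abs(m$fa_impulse_ns - tt$fa_impulse_ns), 2e-3)
    expect_lt(abs(m$strike_duration - tt$strike_duration), 2 / 500)
    # tail extrema compared in magnitude: near-symmetric recoil profiles
    # make the sign of the largest excursion numerically unstable
    expect_lt(rel(abs(m$max_tail_velocity), abs(tt$max_tail_velocity)), 0.02)
    expect_lt(rel(abs(m$max_tail_acceleration),
                  abs(tt$max_tail_acceleration)), 0.05)
    expect_lt(rel(abs(m$max_tail_displacement),
                  abs(tt$max_tail_displacement)), 0.02)
  }
})

test_that("strike distance calibrated at 0.21 m is recovered to a millimetre", {
  tr <- generate_two_mass_trial(noiseless_scenario(D = 0.21, setup = "walled"))
  a <- analyze_strike(tr)
  expect_lt(abs(a$metrics$strike_distance - 0.21), 1e-3)
})

test_that("the total-force maximum dominates every component", {
  for (seed in 1:6) {
    sc <- strike_scenario(setup = if (seed %% 2) "open" else "walled",
                          seed = seed, azimuth = seed / 3)
    a <- analyze_strike(generate_two_mass_trial(sc))
    m <- a$metrics
    expect_gte(m$max_total_force_bw, m$max_vertical_force_bw - 1e-9)
    expect_gte(m$max_total_force_bw, m$max_fa_force_bw - 1e-9)
    expect_gte(m$max_total_force_bw, m$max_lateral_force_bw - 1e-9)
    # slip flags are mutually consistent
    if (m$max_fa_v_ratio <= a$meta$mu) expect_equal(m$pct_above_slip, 0)
    if (m$pct_above_slip > 0) expect_gt(m$max_fa_v_ratio, a$meta$mu)
  }
})

test_that("open-setup slip stays low and walled-setup slip is substantial", {
  pct_open <- vapply(1:10, function(s) {
    a <- analyze_strike(generate_two_mass_trial(
      strike_scenario(setup = "open", seed = s)))
    a$metrics$pct_above_slip
  }, 1)
  expect_lt(mean(pct_open), 5)
  a_w <- analyze_strike(generate_two_mass_trial(
    strike_scenario(setup = "walled", seed = 1)))
  expect_gt(a_w$metrics$pct_above_slip, 0)
  expect_gt(a_w$metrics$max_fa_v_ratio, a_w$meta$mu)
})

test_that("a motionless trial raises a no-strike error", {
  tr <- generate_two_mass_trial(noiseless_scenario(D = 0, setup = "walled"))
  expect_error(analyze_strike(tr), "no strike detected")
})

test_that("analysis objects expose the metric set through methods", {
  tr <- generate_two_mass_trial(strike_scenario(setup = "open", seed = 2))
  a <- analyze_strike(tr)
  cf <- coef(a)
  expect_length(cf, 14)
  expect_named(cf)
  df <- as.data.frame(a)
  expect_equal(df$max_fa_force_bw, unname(cf["max_fa_force_bw"]))
  expect_output(print(a), "Strike analysis")
  expect_output(print(summary(a)), "13 variables")
})
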