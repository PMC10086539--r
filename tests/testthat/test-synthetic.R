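test_that("minimum-jerk ground truth matches the analytic extrema", {
  sc <- noiseless_scenario(D = 0.20, T = 0.10, setup = "walled")
  out <- generate_min_jerk_strike(sc)
  # closed forms: peak speed 1.875 D/T, peak accel (10/sqrt(3)) D/T^2
  expect_equal(out$truth$peak_head_speed, 3.75, tolerance = 1e-12)
  expect_equal(out$truth$peak_head_accel, 115.47, tolerance = 1e-4)
  # numeric oracle: dense evaluation of the velocity polynomial
  tau <- seq(0, 1, by = 1e-5)
  v <- 0.20 / 0.10 * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  expect_equal(max(v), out$truth$peak_head_speed, tolerance = 1e-8)
  # head travels exactly D along the azimuth
  expect_equal(max(out$kin$head_x) - min(out$kin$head_x), 0.20,
               tolerance = 1e-12)
})

test_that("zero-displacement scenario yields constant positions", {
  out <- generate_min_jerk_strike(noiseless_scenario(D = 0, setup = "walled"))
  expect_equal(diff(range(out$kin$head_x)), 0)
  expect_equal(out$truth$peak_head_speed, 0)
})

test_that("too-short strikes are rejected", {
  expect_error(generate_min_jerk_strike(noiseless_scenario(T = 0.005)),
               "4 video frames")
})

test_that("walled two-mass peak force is m_head times peak head acceleration", {
  # peak accel (10/sqrt(3)) D/T^2 = 100 with D below; stationary tail
  Tt <- 0.1
  D <- 100 * Tt^2 / (10 / sqrt(3))
  sc <- noiseless_scenario(D = D, T = Tt, setup = "walled", mass = 0.4,
                           head_mass_fraction = 0.5)
  tr <- generate_two_mass_trial(sc)
  expect_equal(max(abs(tr$series$F_fa)), 0.2 * 100, tolerance = 1e-3)
  expect_true(all(tr$series$a_t == 0))
})

test_that("open-setup noiseless trials never exceed the slip criterion", {
  for (seed in 1:5) {
    sc <- noiseless_scenario(D = 0.15 + 0.02 * seed, T = 0.06 + 0.01 * seed,
                             setup = "open", seed = seed)
    tr <- generate_two_mass_trial(sc)
    expect_lte(max(abs(tr$series$F_fa) / tr$series$F_v), sc$mu + 1e-6)
    expect_equal(tr$truth$pct_above_slip, 0)
  }
})

test_that("ground impulse equals total momentum change on every noiseless trial", {
  for (setup in c("open", "walled")) {
    for (seed in 1:3) {
      sc <- noiseless_scenario(D = 0.1 + 0.05 * seed, T = 0.05 + 0.02 * seed,
                               setup = setup)
      tr <- generate_two_mass_trial(sc)
      s <- tr$series
      imp <- pracma::trapz(s$time, s$F_fa)
      mom <- tr$truth$head_mass * (s$v_h[length(s$v_h)] - s$v_h[1]) +
        tr$truth$tail_mass * (s$v_t[length(s$v_t)] - s$v_t[1])
      denom <- max(abs(mom), tr$truth$head_mass * tr$truth$peak_head_speed)
      expect_lt(abs(imp - mom) / denom, 1e-6)
    }
  }
})

test_that("infeasible open-setup recoil is rejected with the binding sample", {
  sc <- noiseless_scenario(setup = "open", max_tail_accel = 1)
  expect_error(generate_two_mass_trial(sc), "infeasible.*sample")
})

test_that("identical scenario and seed give bit-identical traces", {
  sc1 <- strike_scenario(setup = "open", seed = 42)
  sc2 <- strike_scenario(setup = "open", seed = 42)
  t1 <- generate_two_mass_trial(sc1)
  t2 <- generate_two_mass_trial(sc2)
  expect_identical(t1$force, t2$force)
  expect_identical(t1$kin, t2$kin)
  t3 <- generate_two_mass_trial(strike_scenario(setup = "open", seed = 43))
  expect_false(identical(t1$force, t3$force))
})

test_that("generation does not disturb the session RNG stream", {
  set.seed(99)
  a <- stats::rnorm(1)
  set.seed(99)
  invisible(generate_two_mass_trial(strike_scenario(seed = 7)))
  b <- stats::rnorm(1)
  expect_identical(a, b)
})

test_that("direct-profile half-sine impulse matches the closed form", {
  p <- force_profile("half_sine", amplitude = 1, onset = 0.1, duration = 0.1)
  expect_equal(p$impulse(0.1, 0.2), 2 * 1 * 0.1 / pi, tolerance = 1e-12)
  # trapezoidal quadrature of the sampled profile agrees
  tt <- seq(0, 0.4, by = 1e-3)
  expect_equal(pracma::trapz(tt, p$eval(tt)), 2 * 0.1 / pi, tolerance = 1e-4)
})

test_that("direct-profile trials carry exact calibration truth", {
  tr <- half_sine_trial(fa_bw = 0.64)
  bw <- tr$meta$mass * tr$meta$g
  expect_equal(tr$truth$max_fa_force_bw, 0.64, tolerance = 1e-12)
  expect_equal(tr$truth$fa_impulse_ns, 2 * 0.64 * bw * 0.12 / pi,
               tolerance = 1e-12)
  # piecewise ratio construction: above threshold in exactly 25 of 100 samples
  meta <- trial_meta(setup = "walled", mass = 1)
  g <- meta$g
  tr2 <- generate_direct_profile_trial(
    fa = force_profile("piecewise", breaks = c(0.1, 0.125, 0.2),
                       values = c(0.5 * g, 0)),
    vertical = force_profile("constant", amplitude = 0, baseline = g,
                             onset = 0, duration = 0.3),
    window = c(0.1, 0.1995), meta = meta, t_total = 0.3)
  expect_equal(tr2$truth$pct_above_slip, 25, tolerance = 1e-12)
  # zero-amplitude profiles: all maxima zero
  tr3 <- generate_direct_profile_trial(
    fa = force_profile("zero"),
    vertical = force_profile("constant", amplitude = 0, baseline = g,
                             onset = 0, duration = 0.3),
    window = c(0.1, 0.2), meta = meta, t_total = 0.3)
  expect_equal(tr3$truth$max_fa_force_bw, 0)
  expect_equal(tr3$truth$fa_impulse_ns, 0)
})

test_that("profile support outside the record is an error", {
  meta <- trial_meta()
  expect_error(generate_direct_profile_trial(
    fa = force_profile("half_sine", amplitude = 1, onset = 0.3, duration = 0.5),
    vertical = force_profile("constant", amplitude = 0, baseline = 1,
                             onset = 0, duration = 0.4),
    window = c(0.1, 0.3), meta = meta, t_total = 0.4), "outside the record")
})

test_that("cohort generator is balanced, seeded, and degenerate-exact", {
  d <- generate_cohort(4, 6, seed = 1)
  expect_equal(nrow(d), 48)
  expect_true(all(table(d$individual, d$setup) == 6))
  expect_identical(d, generate_cohort(4, 6, seed = 1))
  # zero SDs: every open trial equals the open cell mean exactly
  d0 <- generate_cohort(3, 4, grand_mean = c(value = 2),
                        setup_effect = c(value = 1),
                        between_individual_sd = 0, interaction_sd = 0,
                        residual_sd = 0, seed = 5)
  expect_true(all(d0$value[d0$setup == "open"] == 2.5))
  expect_true(all(d0$value[d0$setup == "walled"] == 1.5))
  expect_error(generate_cohort(4, 6, residual_sd = -1), ">= 0")
  expect_error(generate_cohort(1, 6), "individuals")
})
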