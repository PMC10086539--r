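# brute-force balanced two-way sums of squares from cell means
.ss_oracle <- function(d) {
  y <- d$value
  ybar <- mean(y)
  ms <- tapply(y, d$setup, mean)
  mi <- tapply(y, d$individual, mean)
  msi <- tapply(y, list(d$setup, d$individual), mean)
  a <- length(ms); b <- length(mi)
  n <- nrow(d) / (a * b)
  ss_s <- b * n * sum((ms - ybar)^2)
  ss_i <- a * n * sum((mi - ybar)^2)
  ss_si <- n * sum((msi - outer(ms, rep(1, b)) - outer(rep(1, a), mi) + ybar)^2)
  ss_e <- sum((y - msi[cbind(as.character(d$setup),
                             as.character(d$individual))])^2)
  list(ss_s = ss_s, ss_i = ss_i, ss_si = ss_si, ss_e = ss_e,
       df = c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (n - 1)))
}

test_that("balanced mixed-ANOVA F-ratios match the textbook EMS oracle", {
  d <- generate_cohort(4, 6, seed = 31)
  f <- mixed_anova(d)
  o <- .ss_oracle(d)
  ms <- c(o$ss_s, o$ss_i, o$ss_si, o$ss_e) / o$df
  expect_equal(f$table$sum_sq, c(o$ss_s, o$ss_i, o$ss_si), tolerance = 1e-9)
  expect_equal(f$table$statistic,
               c(ms[1] / ms[3], ms[2] / ms[3], ms[3] / ms[4]),
               tolerance = 1e-9)
  expect_equal(f$table$den_df, c(3, 3, 40))
  expect_equal(f$table$p,
               stats::pf(f$table$statistic, f$table$df, f$table$den_df,
                         lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("a large setup effect with tiny noise separates cleanly", {
  d <- generate_cohort(4, 6, grand_mean = c(v = 0), setup_effect = c(v = 50),
                       between_individual_sd = 0.1, interaction_sd = 0.1,
                       residual_sd = 0.1, seed = 1)
  f <- mixed_anova(d, "v")
  expect_lt(f$table$p[f$table$term == "setup"], 1e-6)
})

test_that("sparse cells and missing setups are rejected", {
  d <- generate_cohort(4, 6, seed = 2)
  expect_error(mixed_anova(d[d$setup == "open", ]), "both setups")
  d2 <- d[!(d$individual == "I2" & d$setup == "walled" & d$trial > 1), ]
  expect_error(mixed_anova(d2), "individual=I2")
})

test_that("unbalanced designs use the Satterthwaite path", {
  d <- generate_cohort(4, 6, seed = 5)
  d <- d[-c(1, 14, 27), ]
  f <- mixed_anova(d)
  expect_identical(f$method, "REML-Satterthwaite")
  p <- f$table$p
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  # setup F agrees with a direct lmerTest fit (dual route)
  d$.cell <- interaction(d$setup, d$individual)
  ref <- suppressMessages(lmerTest::lmer(value ~ setup + (1 | individual) +
                                           (1 | .cell), data = d))
  expect_equal(f$table$statistic[1], stats::anova(ref)[["F value"]][1],
               tolerance = 1e-8)
})

test_that("Brown-Forsythe matches hand-computed deviation ANOVA", {
  # equal spread: deviations from group medians are identical
  out <- brown_forsythe(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(out$statistic, 0, tolerance = 1e-10)
  expect_equal(out$p, 1, tolerance = 1e-10)
  # extreme spread difference
  out2 <- brown_forsythe(c(rep(0, 10), seq(-10, 10, length.out = 10)),
                         rep(c("a", "b"), each = 10))
  expect_gt(out2$statistic, 5)
  expect_lt(out2$p, 0.05)
  # oracle: one-way ANOVA on |y - median_j| computed explicitly
  set.seed(8)
  y <- stats::rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  z <- unlist(tapply(y, g, function(v) abs(v - stats::median(v))))
  ref <- stats::anova(stats::lm(z ~ gf, data = data.frame(z = z,
                                                          gf = factor(rep(c("a", "b", "c"), each = 10)))))
  out3 <- brown_forsythe(y, g)
  expect_equal(out3$statistic, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(out3$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  # location shift invariance
  y2 <- y + ifelse(g == "a", 100, 0)
  out4 <- brown_forsythe(y2, g)
  expect_equal(out4$statistic, out3$statistic, tolerance = 1e-9)
  expect_error(brown_forsythe(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("Holm step-down matches the hand-worked example and brackets Bonferroni", {
  h <- holm_adjust(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(h$adjusted, c(0.03, 0.06, 0.06))
  expect_identical(h$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_adjust(rep(1, 4))$adjusted, rep(1, 4))
  h1 <- holm_adjust(0.04)
  expect_equal(h1$adjusted, 0.04)
  expect_true(h1$reject)
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotonicity: rejected p never exceed non-rejected p
  set.seed(12)
  for (i in 1:50) {
    p <- stats::runif(8)^2
    h <- holm_adjust(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    raw <- p <= 0.05
    expect_true(all(h$reject[bonf]))        # Holm rejects all Bonferroni rejections
    expect_true(all(raw[h$reject]))         # and only unadjusted-significant ones
    if (any(h$reject) && any(!h$reject))
      expect_lte(max(p[h$reject]), min(p[!h$reject]))
  }
})

test_that("null p-values are uniform at the recorded design size", {
  ps <- vapply(1:400, function(i) {
    d <- generate_cohort(4, 6, between_individual_sd = 0.5,
                         interaction_sd = 0.5, residual_sd = 1, seed = i)
    f <- mixed_anova(d)
    f$table$p[f$table$term == "setup"]
  }, 1)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("variance tests report pooled and per-individual scopes", {
  d <- generate_cohort(3, 5, seed = 9)
  vt <- setup_variance_tests(d)
  expect_equal(nrow(vt), 4)
  expect_identical(vt$scope[1], "pooled")
  expect_true(all(unlist(vt$p) >= 0 & unlist(vt$p) <= 1))
})

test_that("the cohort-level statistical layer flags a planted setup effect", {
  d <- generate_cohort(4, 6,
                       grand_mean = c(quiet = 1, loud = 1),
                       setup_effect = c(quiet = 0, loud = 8),
                       between_individual_sd = 0.3, interaction_sd = 0.3,
                       residual_sd = 0.5, seed = 17)
  st <- strike_stats(d, variables = c("quiet", "loud"))
  tab <- st$table
  expect_true(tab$setup_significant[tab$variable == "loud"])
  expect_false(tab$setup_significant[tab$variable == "quiet"])
  expect_output(print(st), "Holm-corrected")
})
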