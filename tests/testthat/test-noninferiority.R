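test_that("the half-margin-of-error rule reproduces the worked example", {
  # difference reported as 0.3% with 95% margin of error +/- 0.1%
  m <- margin_from_moe(0.001)
  expect_equal(m$delta_prop, 0.0005)
  expect_equal(m$delta_prop * 100, 0.05)

  expect_message(m0 <- margin_from_moe(0), "degenerate")
  expect_equal(m0$delta_prop, 0)

  m2 <- margin_from_ci(0.012, 0.038, 999, 6793)
  half_width <- 1.96 * sqrt(0.012 * 0.988 / 999 + 0.038 * 0.962 / 6793)
  expect_equal(m2$delta_prop, half_width / 2, tolerance = 1e-4)
  expect_equal(m2$provenance, "half-ci-rule")
})

test_that("the proportion-to-log-odds margin conversion is coherent", {
  expect_equal(margin_to_log_or(0.3, 0), 0)
  expect_equal(margin_to_log_or(0.5, 0.1), log(1.5), tolerance = 1e-12)
  tau_c <- 0.038; delta <- 0.005
  direct <- log(((tau_c + delta) / (1 - tau_c - delta)) /
                  (tau_c / (1 - tau_c)))
  expect_equal(margin_to_log_or(tau_c, delta), direct, tolerance = 1e-12)
  # strictly increasing in delta, zero iff delta zero
  deltas <- seq(0, 0.3, by = 0.01)
  vals <- vapply(deltas, function(d) margin_to_log_or(0.05, d), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals[-1] > 0))
  expect_error(margin_to_log_or(0.6, 0.5), "below 1")
})

test_that("the proportions test matches its arithmetic and boundary behavior", {
  res <- test_proportions_ni(5, 500, 10, 500, ni_margin(0.02), alpha = 0.025)
  pt <- 5 / 500; pc <- 10 / 500
  z <- (pt - pc - 0.02) / sqrt(pt * (1 - pt) / 500 + pc * (1 - pc) / 500)
  expect_equal(res$statistic, z, tolerance = 1e-12)
  expect_equal(res$p_value, pnorm(z), tolerance = 1e-12)

  # observed excess exactly at the margin -> z = 0, p = 0.5
  at_margin <- test_proportions_ni(30, 1000, 20, 1000, ni_margin(0.01))
  expect_equal(at_margin$statistic, 0, tolerance = 1e-12)
  expect_equal(at_margin$p_value, 0.5)

  # overwhelming noninferiority
  extreme <- test_proportions_ni(5, 10000, 200, 10000, ni_margin(0.01))
  expect_true(extreme$noninferior)

  expect_error(test_proportions_ni(600, 500, 10, 500, ni_margin(0.01)),
               "exceed")
  expect_error(test_proportions_ni(0, 50, 0, 50, ni_margin(0.01)),
               "zero variance")
})

test_that("the noninferiority p-value is nonincreasing in the margin", {
  deltas <- seq(0, 0.05, by = 0.005)
  ps <- vapply(deltas, function(d) {
    suppressMessages(
      test_proportions_ni(12, 800, 25, 2000, ni_margin(d))$p_value
    )
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("delta = 0 reduces the test to one-sided superiority exactly", {
  suppressMessages({
    ni0 <- test_proportions_ni(12, 800, 25, 2000, ni_margin(0))
  })
  pt <- 12 / 800; pc <- 25 / 2000
  z_sup <- (pt - pc) / sqrt(pt * (1 - pt) / 800 + pc * (1 - pc) / 2000)
  expect_identical(ni0$statistic, z_sup)
  expect_identical(ni0$p_value, pnorm(z_sup))
})

test_that("odds-ratio noninferiority wires the engines to the right tests", {
  preset <- table2_presets("hernia repair", cl_max = 4)
  cohort <- simulate_cohort(preset, n = 6000, seed = 17)
  margin <- margin_from_ci(0.012, 0.038, 999, 6793)

  firth <- test_or_ni(cohort, margin = margin, engine = "firth")
  expect_equal(firth$scale, "log-odds-ratio")
  # rural odds are well below referral odds here: strong noninferiority
  expect_true(firth$noninferior)

  mle <- test_or_ni(cohort, margin = margin, engine = "mle")
  # same direction from both engines
  expect_true(mle$noninferior)

  # mle engine: estimate exactly at the log-odds margin -> one-sided p = 0.5
  fit <- fit_logistic(cohort)
  at_est <- wald_test(fit, null_value = fit$coefficients[["arm"]],
                      sided = "less")
  expect_equal(at_est$p_value, 0.5)
})

test_that("firth-engine odds-ratio noninferiority equals the one-sided PLRT", {
  cohort <- cohort_2x2(4, 196, 18, 382)
  margin <- ni_margin(0.02, tau_c = 18 / 400)
  res <- test_or_ni(cohort, design_arm_only(), margin = margin,
                    engine = "firth")
  direct <- penalized_lrt(cohort, design_arm_only(),
                          null_value = margin$delta_log_or, sided = "less")
  expect_equal(res$p_value, direct$p_value, tolerance = 1e-12)
  expect_equal(res$statistic, direct$statistic, tolerance = 1e-12)
})

test_that("the boundary null holds its one-sided size", {
  # tau_t = tau_c + delta: rejection rate should be ~ alpha
  withr::with_seed(2024, {
    tau_c <- 0.05; delta <- 0.01; alpha <- 0.025
    n_t <- 2000; n_c <- 6000; reps <- 2000
    rej <- logical(reps)
    for (i in seq_len(reps)) {
      et <- rbinom(1, n_t, tau_c + delta)
      ec <- rbinom(1, n_c, tau_c)
      rej[i] <- test_proportions_ni(et, n_t, ec, n_c, ni_margin(delta),
                                    alpha = alpha)$noninferior
    }
    mc_se <- sqrt(alpha * (1 - alpha) / reps)
    expect_lt(abs(mean(rej) - alpha), 3 * mc_se)
  })
})
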