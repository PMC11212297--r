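test_that("power estimates are deterministic and bounded", {
  preset <- table2_presets("hernia repair", cl_max = 4)
  a <- estimate_power(preset, n = 1500, replications = 25, seed = 4)
  b <- estimate_power(preset, n = 1500, replications = 25, seed = 4)
  expect_identical(a, b)
  expect_true(a$power >= 0 && a$power <= 1)
  expect_equal(a$mc_se, sqrt(a$power * (1 - a$power) / 25))

  one <- estimate_power(preset, n = 1500, replications = 1, seed = 4)
  expect_true(one$power %in% c(0, 1))
})

test_that("both engines see identical cohorts within a replication", {
  preset <- table2_presets("appendectomy", cl_max = 4)
  both <- ruralni:::.power_pvalues(preset, 800, 10, seed = 6,
                                   engines = c("mle", "firth"))
  firth_only <- ruralni:::.power_pvalues(preset, 800, 10, seed = 6,
                                         engines = "firth")
  mle_only <- ruralni:::.power_pvalues(preset, 800, 10, seed = 6,
                                       engines = "mle")
  # the per-replication seed stream does not depend on which engines run,
  # so every engine sees the same cohorts
  expect_identical(both$p_firth, firth_only$p_firth)
  expect_identical(both$p_mle, mle_only$p_mle)
})

test_that("a null facility effect rejects at about the test size", {
  null_preset <- scenario_preset("appendectomy", 0, 2392, 134, 0.03, 0.03)
  est <- estimate_power(null_preset, engine = "firth", replications = 400,
                        alpha = 0.05, seed = 8)
  mc_se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(est$power - 0.05), 3 * mc_se)
})

test_that("a degenerate event-free scenario reports zero power with a warning", {
  dead <- scenario_preset("hernia repair", 4, 1000, 130, 0, 0)
  expect_warning(est <- estimate_power(dead, replications = 10, seed = 1),
                 "degenerate")
  expect_equal(est$power, 0)
})

test_that("power grows with the sample size under a real effect", {
  preset <- table2_presets("hernia repair", cl_max = 4)
  curve <- power_curve(preset, n_values = c(1000, 3000, 7792),
                       engines = "firth", replications = 120, seed = 10)
  expect_s3_class(curve, "rni_power_curve")
  pooled_se <- sqrt(sum(curve$mc_se^2))
  expect_gt(curve$power[3], curve$power[1] - 3 * pooled_se)
  expect_gt(curve$power[3], 0.9)  # effect is strong at the available n
})

test_that("minimum-n search honors trivial and sentinel cases", {
  preset <- table2_presets("hernia repair", cl_max = 4)
  # power at the grid floor is already ~1 for a huge effect
  strong <- scenario_preset("hernia repair", 4, 8000, 1000, 0.01, 0.15)
  mn <- min_sample_size(strong, engine = "firth", grid_lo = 500,
                        grid_hi = 4000, resolution = 10,
                        replications = 60, seed = 12)
  expect_equal(mn$n_min, 500)
  expect_false(mn$above_grid)

  # equal proportions never reach 0.8: sentinel
  null_preset <- scenario_preset("appendectomy", 0, 2392, 134, 0.03, 0.03)
  sent <- min_sample_size(null_preset, engine = "firth", grid_lo = 500,
                          grid_hi = 2000, resolution = 10,
                          replications = 60, seed = 12)
  expect_true(sent$above_grid)
  expect_identical(sent$n_min, Inf)
  expect_equal(sent$label, ">2000")
})

test_that("minimum-n agrees with the two-proportion closed form within 2x", {
  # analytic n for a two-proportion z-test at power 0.8, alpha 0.05 two-sided
  preset <- scenario_preset("hernia repair", 4, 8000, 1000, 0.02, 0.06)
  f <- preset$rural_fraction
  p1 <- 0.02; p2 <- 0.06
  pbar <- f * p1 + (1 - f) * p2
  # unequal-allocation variance, solve (z_a/2 + z_b)^2 * v(n) = diff^2
  v1 <- p1 * (1 - p1) / f + p2 * (1 - p2) / (1 - f)
  n_analytic <- (qnorm(0.975) + qnorm(0.8))^2 * v1 / (p1 - p2)^2
  mn <- min_sample_size(preset, engine = "mle", grid_lo = 200,
                        grid_hi = 8000, resolution = 10,
                        replications = 250, seed = 14)
  expect_false(mn$above_grid)
  expect_gt(mn$n_min, n_analytic / 2)
  expect_lt(mn$n_min, n_analytic * 2)
})

test_that("the power table has one row per scenario and sane columns", {
  empty <- run_power_table(table2_presets()[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("power_mle", "power_firth") %in% names(empty)))

  one <- run_power_table(table2_presets("appendectomy", cl_max = 0),
                         replications = 40, seed = 16)
  expect_equal(nrow(one), 1L)
  expect_true(one$power_mle >= 0 && one$power_firth <= 1)

  two <- run_power_table(table2_presets("cesarean delivery")[1:2, ],
                         replications = 25, seed = 16)
  expect_equal(nrow(two), 2L)
})
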