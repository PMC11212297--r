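test_that("intercept-only Firth fit matches the Jeffreys-mode closed form", {
  for (case in list(c(k = 25, n = 100), c(k = 1, n = 50), c(k = 0, n = 40))) {
    k <- case[["k"]]; n <- case[["n"]]
    d <- tibble::tibble(event = c(rep(1, k), rep(0, n - k)))
    fit <- fit_firth(d, design_spec(treatment = NULL))
    expected <- log((k + 0.5) / (n - k + 0.5))
    expect_equal(unname(fit$coefficients[["(Intercept)"]]), expected,
                 tolerance = 1e-6)
    # implied event probability (k + 1/2)/(n + 1)
    expect_equal(unname(plogis(fit$coefficients[["(Intercept)"]])),
                 (k + 0.5) / (n + 1), tolerance = 1e-6)
    # against the independent 1-D penalized-likelihood maximizer
    X <- matrix(1, n, 1)
    expect_equal(unname(fit$coefficients[["(Intercept)"]]),
                 oracle_max_1d(X, d$event)$maximum, tolerance = 1e-5)
  }
})

test_that("2x2 Firth treatment coefficient equals the Haldane-corrected log-OR", {
  withr::with_seed(99, {
    for (i in 1:50) {
      a <- sample(0:8, 1); b <- sample(1:12, 1)
      c <- sample(0:8, 1); d <- sample(1:12, 1)
      if (a + c == 0) a <- 1
      cohort <- cohort_2x2(a, b, c, d)
      fit <- fit_firth(cohort, design_arm_only())
      haldane <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
      expect_equal(unname(fit$coefficients[["arm"]]), haldane,
                   tolerance = 1e-6)
    }
  })
  # spot-check one table against the independent 2-D maximizer
  cohort <- cohort_2x2(3, 7, 9, 1)
  fit <- fit_firth(cohort, design_arm_only())
  X <- cbind(1, cohort$arm)
  opt <- oracle_max_2d(X, cohort$event, start = c(0, 0))
  expect_equal(unname(fit$coefficients[["arm"]]), opt$par[2], tolerance = 1e-4)
})

test_that("Firth estimates stay finite and converged under degenerate outcomes", {
  sep <- fit_firth(separation_cohort(), design_arm_only())
  expect_true(sep$converged)
  expect_true(all(is.finite(sep$coefficients)))

  all_events <- tibble::tibble(event = rep(1, 20), arm = rep(c(0, 1), 10))
  f1 <- fit_firth(all_events, design_arm_only())
  expect_true(all(is.finite(f1$coefficients)))
  no_events <- tibble::tibble(event = rep(0, 20), arm = rep(c(0, 1), 10))
  f0 <- fit_firth(no_events, design_arm_only())
  expect_true(all(is.finite(f0$coefficients)))
})

test_that("MLE engine recovers closed forms and flags separation", {
  d <- tibble::tibble(event = c(rep(1, 25), rep(0, 75)))
  fit <- fit_logistic(d, design_spec(treatment = NULL))
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(25 / 75),
               tolerance = 1e-6)

  cohort <- cohort_2x2(3, 7, 9, 1)
  fit2 <- fit_logistic(cohort, design_arm_only())
  expect_equal(unname(fit2$coefficients[["arm"]]), log((3 * 1) / (7 * 9)),
               tolerance = 1e-6)

  expect_warning(
    sep <- fit_logistic(separation_cohort(), design_arm_only()),
    "separation"
  )
  expect_true(sep$separation)
  expect_false(sep$converged)

  expect_error(
    fit_logistic(tibble::tibble(event = rep(1, 10), arm = rep(0:1, 5)),
                 design_arm_only()),
    "single class"
  )
})

test_that("degenerate designs are rejected with the offending column named", {
  d <- tibble::tibble(event = rep(0:1, 10), arm = rep(0:1, 10), z = 3)
  expect_error(fit_firth(d, design_spec(covariates = "z")), "z")
  d2 <- tibble::tibble(event = rep(0:1, 10), arm = rep(0:1, 10))
  d2$dup <- d2$arm
  expect_error(fit_firth(d2, design_spec(covariates = "dup")),
               "rank-deficient|dup")
})

test_that("relabeling the arms negates the treatment coefficient exactly", {
  withr::with_seed(5, {
    cohort <- tibble::tibble(
      event = rbinom(300, 1, 0.2),
      arm = rbinom(300, 1, 0.3)
    )
  })
  fit <- fit_firth(cohort, design_arm_only())
  flipped <- dplyr::mutate(cohort, arm = 1 - arm)
  fit2 <- fit_firth(flipped, design_arm_only())
  expect_equal(unname(fit$coefficients[["arm"]]),
               -unname(fit2$coefficients[["arm"]]), tolerance = 1e-8)
})

test_that("Firth and MLE agree on abundant, well-behaved data", {
  withr::with_seed(21, {
    n <- 10000
    x <- rbinom(n, 1, 0.5)
    cohort <- tibble::tibble(
      arm = x,
      event = rbinom(n, 1, plogis(-0.8 + 0.5 * x))
    )
  })
  firth <- fit_firth(cohort, design_arm_only())
  mle <- fit_logistic(cohort, design_arm_only())
  expect_lt(max(abs(firth$coefficients - mle$coefficients)), 0.02)
})

test_that("Wald tests follow the normal reference in both tails", {
  withr::with_seed(31, {
    cohort <- tibble::tibble(arm = rbinom(400, 1, 0.5),
                             event = rbinom(400, 1, 0.3))
  })
  fit <- fit_logistic(cohort, design_arm_only())
  est <- fit$coefficients[["arm"]]
  # null at the estimate: two-sided p = 1
  at_est <- wald_test(fit, null_value = est)
  expect_equal(at_est$p_value, 1)
  expect_equal(at_est$statistic, 0)
  # z = 1.96 by construction
  se <- fit$se[["arm"]]
  p196 <- wald_test(fit, null_value = est - 1.96 * se)$p_value
  expect_equal(p196, 2 * pnorm(-1.96), tolerance = 1e-10)
  # hand-computed example: estimate -0.9, se 0.3 -> z = -3
  expect_equal(2 * pnorm(-abs((-0.9 - 0) / 0.3)), 2 * pnorm(-3))
  # one-sided orientation
  expect_lt(wald_test(fit, null_value = est + 1, sided = "less")$p_value, 0.5)
  expect_gt(wald_test(fit, null_value = est + 1, sided = "greater")$p_value, 0.5)
})

test_that("penalized LRT is zero at the estimate and matches the grid oracle", {
  cohort <- cohort_2x2(4, 16, 10, 10)
  fit <- fit_firth(cohort, design_arm_only())
  at_est <- penalized_lrt(cohort, design_arm_only(),
                          null_value = fit$coefficients[["arm"]])
  expect_equal(at_est$statistic, 0, tolerance = 1e-6)
  expect_equal(at_est$p_value, 1, tolerance = 1e-4)

  # separation fixture: statistic equals twice the penalized-LL drop computed
  # by independent profile maximization over the intercept
  sep <- separation_cohort()
  tst <- penalized_lrt(sep, design_arm_only(), null_value = 0)
  X <- cbind(1, sep$arm)
  full <- oracle_max_2d(X, sep$event, start = c(-1, 2))
  profile_null <- stats::optimize(
    function(b0) oracle_pen_ll(X, sep$event, c(b0, 0)),
    c(-10, 10), maximum = TRUE, tol = 1e-10
  )
  expect_equal(tst$statistic, 2 * (-full$value - profile_null$objective),
               tolerance = 1e-3)
  expect_true(is.finite(tst$statistic))
})

test_that("penalized LRT statistic is nonnegative across random tables", {
  withr::with_seed(77, {
    for (i in 1:20) {
      a <- sample(0:6, 1); b <- sample(2:12, 1)
      c <- sample(0:6, 1); d <- sample(2:12, 1)
      cohort <- cohort_2x2(a, b, c, d)
      null <- rnorm(1)
      tst <- penalized_lrt(cohort, design_arm_only(), null_value = null)
      expect_gte(tst$statistic, 0)
      expect_true(tst$p_value >= 0 && tst$p_value <= 1)
    }
  })
})

test_that("one-sided penalized LRT follows the signed-root convention", {
  cohort <- cohort_2x2(4, 16, 10, 10)  # arm coefficient below zero
  two <- penalized_lrt(cohort, design_arm_only(), null_value = 0)
  less <- penalized_lrt(cohort, design_arm_only(), null_value = 0,
                        sided = "less")
  greater <- penalized_lrt(cohort, design_arm_only(), null_value = 0,
                           sided = "greater")
  expect_equal(less$p_value, two$p_value / 2)
  expect_equal(greater$p_value, 1 - two$p_value / 2)
  # chi-square(1) quantile sanity: statistic 3.84 <-> p ~ 0.05
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
})
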