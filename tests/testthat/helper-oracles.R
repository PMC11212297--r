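# Independent oracles used across tests: the penalized log-likelihood is
# evaluated directly (determinant via det()) and maximized by grid/optimize,
# never through the package's Newton engine.

oracle_pen_ll <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pii <- plogis(eta)
  W <- diag(pii * (1 - pii), nrow = length(y))
  ll <- sum(y * eta - log1p(exp(eta)))
  ll + 0.5 * log(det(t(X) %*% W %*% X))
}

# 1-D maximization (intercept-only or a single fixed-direction coefficient)
oracle_max_1d <- function(X, y, lower = -10, upper = 10) {
  stats::optimize(function(b) oracle_pen_ll(X, y, b), c(lower, upper),
                  maximum = TRUE, tol = 1e-10)
}

# 2-D grid + Nelder-Mead polish for (intercept, slope) designs
oracle_max_2d <- function(X, y, start = c(0, 0)) {
  stats::optim(start, function(b) -oracle_pen_ll(X, y, b),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
}

# a 2x2 cohort: a/b events/non-events in arm 1, c/d in arm 0
cohort_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    event = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    arm = c(rep(1, a + b), rep(0, c + d))
  )
}

design_arm_only <- function() design_spec(covariates = character())

separation_cohort <- function() {
  tibble::tibble(event = c(0, 0, 1, 1), arm = c(0, 0, 1, 1))
}
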