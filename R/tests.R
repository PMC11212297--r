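.new_test <- function(kind, statistic, p_value, null_value, estimate, sided) {
  structure(
    list(kind = kind, statistic = statistic, p_value = p_value,
         null_value = null_value, estimate = estimate, sided = sided),
    class = "rni_test"
  )
}

.match_sided <- function(sided) {
  match.arg(sided, c("two.sided", "greater", "less"))
}

#' Wald test on a fitted coefficient
#'
#' Tests a point null on one coefficient of a fitted model using the normal
#' reference for `z = (estimate - null_value) / SE`. One-sided alternatives
#' follow the base-R convention: `sided = "less"` means H1: coefficient <
#' `null_value` - the alternative used for noninferiority on the log-odds
#' scale.
#'
#' @param fit An `rni_fit` from [fit_logistic()] or [fit_firth()].
#' @param coefficient Coefficient name; defaults to the design's treatment
#'   column.
#' @param null_value Null value on the log-odds scale (default 0).
#' @param sided `"two.sided"`, `"greater"` or `"less"` (direction of H1).
#' @return An `rni_test` object; `tidy()` gives a one-row tibble.
#' @export
wald_test <- function(fit, coefficient = NULL, null_value = 0,
                      sided = "two.sided") {
  sided <- .match_sided(sided)
  coefficient <- coefficient %||% fit$design$treatment
  if (is.null(coefficient)) abort("specify `coefficient`.")
  if (!coefficient %in% names(fit$coefficients)) {
    abort(sprintf("no coefficient named `%s` in the fit.", coefficient))
  }
  if (fit$separation) {
    warn("Wald test on a separated fit is unreliable; prefer penalized_lrt().")
  }
  se <- fit$se[[coefficient]]
  if (!is.finite(se) || se <= 0) abort("standard error is zero or undefined.")
  est <- fit$coefficients[[coefficient]]
  z <- (est - null_value) / se
  p <- switch(sided,
    two.sided = 2 * pnorm(-abs(z)),
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z)
  )
  .new_test(paste0("wald-", sided), z, p, null_value, est, sided)
}

# penalized LRT statistic from full + constrained Firth fits on a prepared
# design; returns statistic, estimate, and the two fits' penalized logliks
.plrt_core <- function(X, y, coef_index, null_value, full = NULL) {
  full <- full %||% .firth_newton(X, y)
  start <- full$beta
  start[coef_index] <- null_value
  constrained <- .firth_newton(
    X, y, fixed = coef_index, fixed_value = null_value, beta0 = start
  )
  if (!constrained$converged) {
    abort(sprintf(
      "constrained Firth fit at null %.6g did not converge (%d iterations).",
      null_value, constrained$iterations
    ))
  }
  list(
    statistic = max(0, 2 * (full$loglik - constrained$loglik)),
    estimate = full$beta[[coef_index]],
    full = full, constrained = constrained
  )
}

#' Penalized likelihood-ratio test on a Firth coefficient
#'
#' Tests H0: coefficient = `null_value` by comparing the maximized penalized
#' log-likelihood with a constrained refit that holds the named coefficient
#' at the null (via a fixed-coefficient Newton fit; the Jeffreys penalty
#' keeps using the full-design information). The two-sided p-value comes
#' from the chi-square distribution with 1 df; one-sided p-values use the
#' signed-root convention - half the two-sided p when the estimate lies on
#' the alternative's side of the null, one minus half otherwise. This is the
#' test the Firth engine uses for both the facility-effect power analysis
#' and noninferiority on adjusted odds ratios.
#'
#' @inheritParams fit_firth
#' @param coefficient Coefficient name; defaults to the design's treatment
#'   column.
#' @param null_value Null value on the log-odds scale (default 0).
#' @param sided `"two.sided"`, `"greater"` or `"less"` (direction of H1).
#' @return An `rni_test` object; `tidy()` gives a one-row tibble.
#' @examples
#' d <- tibble::tibble(event = c(0, 0, 1, 1), arm = c(0, 0, 1, 1))
#' penalized_lrt(d, design_spec(covariates = character()))
#' @export
penalized_lrt <- function(data, design = NULL, coefficient = NULL,
                          null_value = 0, sided = "two.sided") {
  sided <- .match_sided(sided)
  design <- design %||% .design_for_cohort(data)
  coefficient <- coefficient %||% design$treatment
  if (is.null(coefficient)) abort("specify `coefficient`.")
  dd <- .build_design(data, design)
  if (!coefficient %in% colnames(dd$X)) {
    abort(sprintf("no coefficient named `%s` in the design.", coefficient))
  }
  core <- .plrt_core(dd$X, dd$y, match(coefficient, colnames(dd$X)), null_value)
  p2 <- pchisq(core$statistic, df = 1, lower.tail = FALSE)
  p <- switch(sided,
    two.sided = p2,
    greater = if (core$estimate > null_value) p2 / 2 else 1 - p2 / 2,
    less = if (core$estimate < null_value) p2 / 2 else 1 - p2 / 2
  )
  .new_test(paste0("plrt-", sided), core$statistic, p, null_value,
            core$estimate, sided)
}

#' @export
print.rni_test <- function(x, ...) {
  cat(sprintf(
    "<%s>  statistic = %.4g, p = %.4g  (null %.4g, estimate %.4g)\n",
    x$kind, x$statistic, x$p_value, x$null_value, x$estimate
  ))
  invisible(x)
}

#' @rdname wald_test
#' @param x An `rni_test`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rni_test <- function(x, ...) {
  tibble(
    kind = x$kind, statistic = x$statistic, p.value = x$p_value,
    null.value = x$null_value, estimate = x$estimate
  )
}
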