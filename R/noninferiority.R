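#' Noninferiority margins for rare adverse-event comparisons
#'
#' A noninferiority margin is the largest excess in the treatment arm's
#' adverse-event proportion over control that would still be considered
#' clinically meaningless. The package's margin rule is conservative: take
#' the 95% confidence interval for the control-minus-treatment difference
#' in proportions and set the proportion-scale margin to **half its
#' half-width** (half the margin of error). A reported difference of
#' 0.3% +/- 0.1% therefore yields delta = 0.05%.
#'
#' `margin_from_ci()` computes the Wald half-width from the observed
#' proportions and arm sizes; `margin_from_moe()` accepts a margin of error
#' quoted directly (e.g. from a historical study); `ni_margin()` wraps a
#' user-supplied delta. When a control proportion is available the margin is
#' also expressed on the log-odds scale via [margin_to_log_or()], for tests
#' on adjusted odds ratios.
#'
#' @param tau_t,tau_c Treatment and control event proportions.
#' @param n_t,n_c Arm sample sizes.
#' @param conf_level Confidence level of the difference CI (default 0.95).
#' @param moe Margin of error (CI half-width) for the difference, on the
#'   proportion scale.
#' @param delta_prop Proportion-scale margin delta, user-supplied.
#' @return An `rni_margin` object: `delta_prop`, `tau_c` (if known),
#'   `delta_log_or` (if computable), `moe`, and `provenance`.
#' @examples
#' # the half-margin-of-error rule on a difference reported as 0.3% +/- 0.1%
#' margin_from_moe(0.001)
#' @export
margin_from_ci <- function(tau_t, tau_c, n_t, n_c, conf_level = 0.95) {
  .check_prob(tau_t, "tau_t")
  .check_prob(tau_c, "tau_c")
  .check_count(n_t, "n_t")
  .check_count(n_c, "n_c")
  z <- qnorm(1 - (1 - conf_level) / 2)
  moe <- z * sqrt(tau_t * (1 - tau_t) / n_t + tau_c * (1 - tau_c) / n_c)
  .new_margin(moe / 2, tau_c = tau_c, moe = moe, provenance = "half-ci-rule")
}

#' @rdname margin_from_ci
#' @export
margin_from_moe <- function(moe, tau_c = NULL) {
  if (!is.numeric(moe) || length(moe) != 1L || moe < 0) {
    abort("`moe` must be a single nonnegative number.")
  }
  .new_margin(moe / 2, tau_c = tau_c, moe = moe, provenance = "half-ci-rule")
}

#' @rdname margin_from_ci
#' @export
ni_margin <- function(delta_prop, tau_c = NULL) {
  if (!is.numeric(delta_prop) || length(delta_prop) != 1L || delta_prop < 0) {
    abort("`delta_prop` must be a single nonnegative number.")
  }
  .new_margin(delta_prop, tau_c = tau_c, moe = NA_real_,
              provenance = "user-supplied")
}

.new_margin <- function(delta_prop, tau_c = NULL, moe = NA_real_,
                        provenance = "user-supplied") {
  if (!is.null(tau_c)) .check_prob(tau_c, "tau_c")
  delta_log_or <- if (!is.null(tau_c) && tau_c > 0 && tau_c + delta_prop < 1) {
    margin_to_log_or(tau_c, delta_prop)
  } else {
    NA_real_
  }
  if (delta_prop == 0) {
    inform("degenerate margin: delta = 0 collapses noninferiority to one-sided superiority.")
  }
  structure(
    list(delta_prop = delta_prop, tau_c = tau_c %||% NA_real_,
         delta_log_or = delta_log_or, moe = moe, provenance = provenance),
    class = "rni_margin"
  )
}

#' Convert a proportion-scale margin to the log-odds scale
#'
#' Noninferiority on an adjusted odds ratio needs the margin on the
#' log-odds scale. The conversion anchors at the control event proportion:
#' the log-odds margin is the log odds ratio produced by lifting the control
#' proportion by delta,
#' `log( ((tau_c + delta) / (1 - tau_c - delta)) / (tau_c / (1 - tau_c)) )`.
#' This mapping is one defensible reading of how a proportion-scale margin
#' carries over to regression coefficients; it is strictly increasing in
#' delta and zero iff delta is zero.
#'
#' @param tau_c Control event proportion, in (0, 1).
#' @param delta_prop Proportion-scale margin, with `tau_c + delta_prop < 1`.
#' @return The log-odds-scale margin (a nonnegative number for
#'   `delta_prop >= 0`).
#' @export
margin_to_log_or <- function(tau_c, delta_prop) {
  if (!is.numeric(tau_c) || length(tau_c) != 1L || tau_c <= 0 || tau_c >= 1) {
    abort("`tau_c` must be in (0, 1).")
  }
  if (tau_c + delta_prop >= 1) {
    abort("`tau_c + delta_prop` must be below 1.")
  }
  lifted <- tau_c + delta_prop
  log((lifted / (1 - lifted)) / (tau_c / (1 - tau_c)))
}

#' @export
print.rni_margin <- function(x, ...) {
  cat(sprintf(
    "<noninferiority margin>  delta = %.6g (proportion scale), provenance: %s\n",
    x$delta_prop, x$provenance
  ))
  if (is.finite(x$delta_log_or)) {
    cat(sprintf("  log-odds scale: %.6g (control proportion %.4g)\n",
                x$delta_log_or, x$tau_c))
  }
  invisible(x)
}

#' @rdname margin_from_ci
#' @param x An `rni_margin`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rni_margin <- function(x, ...) {
  tibble(
    delta_prop = x$delta_prop, tau_c = x$tau_c,
    delta_log_or = x$delta_log_or, moe = x$moe, provenance = x$provenance
  )
}

.new_ni <- function(margin, scale, statistic, p_value, alpha, estimate,
                    engine = NA_character_) {
  structure(
    list(margin = margin, scale = scale, statistic = statistic,
         p_value = p_value, noninferior = p_value < alpha, alpha = alpha,
         estimate = estimate, engine = engine),
    class = "rni_ni"
  )
}

#' Noninferiority test for two adverse-event proportions
#'
#' One-sided Wald z-test of H0: `tau_t - tau_c >= delta` against H1:
#' `tau_t - tau_c < delta` - the treatment arm's excess event proportion is
#' at least the margin, versus smaller. Rejecting H0 is evidence of
#' noninferiority. With `delta = 0` this is exactly the ordinary one-sided
#' superiority test.
#'
#' @param events_t,n_t Events and visits in the treatment (rural) arm.
#' @param events_c,n_c Events and visits in the control (referral) arm.
#' @param margin An `rni_margin` (or a bare nonnegative number, taken as the
#'   proportion-scale delta).
#' @param alpha One-sided level (default 0.025, the clinical-trial
#'   convention).
#' @return An `rni_ni` object; `tidy()` gives a one-row tibble.
#' @examples
#' test_proportions_ni(5, 500, 10, 500, margin = ni_margin(0.02))
#' @export
test_proportions_ni <- function(events_t, n_t, events_c, n_c, margin,
                                alpha = 0.025) {
  margin <- .as_margin(margin)
  .check_count(n_t, "n_t")
  .check_count(n_c, "n_c")
  .check_count(events_t, "events_t", min = 0L)
  .check_count(events_c, "events_c", min = 0L)
  if (events_t > n_t || events_c > n_c) abort("events cannot exceed visits.")
  .check_prob(alpha, "alpha")
  pt <- events_t / n_t
  pc <- events_c / n_c
  v <- pt * (1 - pt) / n_t + pc * (1 - pc) / n_c
  if (v <= 0) {
    abort("zero variance: no events and no non-events to compare.")
  }
  z <- (pt - pc - margin$delta_prop) / sqrt(v)
  .new_ni(margin, "proportion", z, pnorm(z), alpha, estimate = pt - pc)
}

#' Noninferiority test on an adjusted odds ratio
#'
#' Tests H0: `beta_treatment >= delta_log_or` (the adjusted log odds ratio of
#' an adverse event at a rural versus referral facility is at least the
#' margin) against H1: it is smaller. The margin arrives on the proportion
#' scale and is converted through the control proportion (see
#' [margin_to_log_or()]); the control proportion defaults to the margin's,
#' else the observed referral-arm event proportion. The `"mle"` engine uses
#' a one-sided Wald test; the `"firth"` engine uses the one-sided penalized
#' likelihood-ratio test at the shifted null - penalized fits need
#' likelihood-ratio inference, a Wald test only suffices for the ordinary
#' MLE.
#'
#' @inheritParams fit_firth
#' @param margin An `rni_margin` (or bare proportion-scale delta).
#' @param engine `"firth"` (default) or `"mle"`.
#' @param alpha One-sided level (default 0.025).
#' @return An `rni_ni` object; `tidy()` gives a one-row tibble.
#' @export
test_or_ni <- function(data, design = NULL, margin, engine = c("firth", "mle"),
                       alpha = 0.025) {
  engine <- match.arg(engine)
  margin <- .as_margin(margin)
  design <- design %||% .design_for_cohort(data)
  .check_prob(alpha, "alpha")
  delta_log_or <- margin$delta_log_or
  if (!is.finite(delta_log_or)) {
    dd0 <- .build_design(data, design)
    tau_c <- mean(dd0$y[dd0$X[, design$treatment] == 0])
    if (tau_c <= 0 || tau_c + margin$delta_prop >= 1) {
      abort(paste(
        "cannot place the margin on the log-odds scale: control proportion",
        "is 0 or the lifted proportion reaches 1; supply a margin with `tau_c`."
      ))
    }
    margin$tau_c <- tau_c
    margin$delta_log_or <- delta_log_or <- margin_to_log_or(tau_c, margin$delta_prop)
  }
  if (margin$delta_prop == 0) {
    inform("delta = 0: this is a one-sided superiority test, not noninferiority.")
  }
  if (engine == "firth") {
    tst <- penalized_lrt(data, design, null_value = delta_log_or, sided = "less")
  } else {
    fit <- fit_logistic(data, design)
    tst <- wald_test(fit, null_value = delta_log_or, sided = "less")
  }
  .new_ni(margin, "log-odds-ratio", tst$statistic, tst$p_value, alpha,
          estimate = tst$estimate, engine = engine)
}

.as_margin <- function(margin) {
  if (inherits(margin, "rni_margin")) return(margin)
  if (is.numeric(margin) && length(margin) == 1L) {
    return(suppressMessages(ni_margin(margin)))
  }
  abort("`margin` must be an rni_margin or a single nonnegative number.")
}

#' @export
print.rni_ni <- function(x, ...) {
  cat(sprintf(
    "<noninferiority test, %s scale%s>\n", x$scale,
    if (!is.na(x$engine)) paste0(", ", x$engine, " engine") else ""
  ))
  cat(sprintf("  H0: excess >= delta  (delta = %.6g%s)\n",
              x$margin$delta_prop,
              if (is.finite(x$margin$delta_log_or)) {
                sprintf(", log-odds %.6g", x$margin$delta_log_or)
              } else ""))
  cat(sprintf(
    "  statistic = %.4g, one-sided p = %.4g -> %s at alpha = %g\n",
    x$statistic, x$p_value,
    if (x$noninferior) "noninferior" else "noninferiority NOT shown", x$alpha
  ))
  invisible(x)
}

#' @rdname test_proportions_ni
#' @param x An `rni_ni`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rni_ni <- function(x, ...) {
  tibble(
    scale = x$scale, engine = x$engine,
    delta_prop = x$margin$delta_prop, delta_log_or = x$margin$delta_log_or,
    estimate = x$estimate, statistic = x$statistic, p.value = x$p_value,
    alpha = x$alpha, noninferior = x$noninferior
  )
}
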