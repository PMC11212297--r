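#' E-value sensitivity analysis for an adjusted odds ratio
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need with both the facility
#' type and the adverse-event outcome to fully explain away an observed
#' adjusted odds ratio. For a risk ratio RR >= 1 it is
#' `RR + sqrt(RR * (RR - 1))`; for RR < 1 the formula is applied to 1/RR,
#' making the E-value symmetric in the effect direction and always at least
#' 1 (with E = 1 exactly at the null). Because the outcomes here are rare
#' (all under 4%), the odds ratio is treated as a risk ratio by default
#' (`rare_outcome = TRUE`); for common outcomes the square-root
#' approximation `RR = sqrt(OR)` is available instead.
#'
#' The confidence-interval E-value uses the CI limit closer to the null and
#' is 1 when the interval crosses 1: no unmeasured confounding at all is
#' needed to explain an effect whose interval already includes the null.
#'
#' @param or_point Adjusted odds ratio point estimate (> 0).
#' @param ci_lo,ci_hi Optional 95% confidence limits (`ci_lo <= or_point <=
#'   ci_hi`).
#' @param rare_outcome Treat the OR as a risk ratio (default `TRUE`)?
#'   Otherwise use `RR = sqrt(OR)`.
#' @return A one-row tibble: `or_point`, `or_ci_limit` (the limit closer to
#'   1, `NA` without a CI), `e_value_point`, `e_value_ci`.
#' @examples
#' e_value(2)                    # 2 + sqrt(2)
#' e_value(1.1, 0.8, 1.5)        # CI crosses 1: e_value_ci = 1
#' @export
e_value <- function(or_point, ci_lo = NULL, ci_hi = NULL,
                    rare_outcome = TRUE) {
  if (!is.numeric(or_point) || length(or_point) != 1L || or_point <= 0) {
    abort("`or_point` must be a single positive number.")
  }
  has_ci <- !is.null(ci_lo) || !is.null(ci_hi)
  if (has_ci) {
    if (is.null(ci_lo) || is.null(ci_hi)) {
      abort("supply both `ci_lo` and `ci_hi`, or neither.")
    }
    if (ci_lo <= 0 || ci_hi <= 0) abort("confidence limits must be positive.")
    if (ci_lo > or_point || ci_hi < or_point) {
      abort("need `ci_lo <= or_point <= ci_hi`.")
    }
  }
  to_rr <- function(or) if (rare_outcome) or else sqrt(or)
  e_of <- function(rr) {
    if (rr < 1) rr <- 1 / rr
    rr + sqrt(rr * (rr - 1))
  }
  e_point <- e_of(to_rr(or_point))
  if (has_ci) {
    if (ci_lo <= 1 && ci_hi >= 1) {
      limit <- NA_real_
      e_ci <- 1
    } else {
      # the limit closer to the null
      limit <- if (ci_lo > 1) ci_lo else ci_hi
      e_ci <- e_of(to_rr(limit))
    }
  } else {
    limit <- NA_real_
    e_ci <- NA_real_
  }
  tibble(
    or_point = or_point, or_ci_limit = limit,
    e_value_point = e_point, e_value_ci = e_ci
  )
}
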