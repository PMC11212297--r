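#' Describe a simulated patient covariate
#'
#' A covariate specification records how one explanatory variable is drawn in
#' the cohort simulator: either normal (`"continuous"`, with a mean and
#' standard deviation) or Bernoulli (`"binary"`, with a success probability),
#' separately for the rural and referral arms. Simulated covariates carry no
#' effect on the adverse-event outcome; they reproduce the confounder
#' structure a real analysis would adjust for, not a causal signal.
#'
#' @param name Column name the covariate will take in the simulated cohort.
#' @param kind `"continuous"` (normal) or `"binary"` (Bernoulli).
#' @param mean,sd Normal parameters, used for both arms unless overridden.
#' @param prob Bernoulli success probability, both arms unless overridden.
#' @param rural,referral Optional per-arm overrides: a list with `mean`/`sd`
#'   (continuous) or `prob` (binary).
#' @return A one-row tibble with columns `name`, `kind` and per-arm
#'   parameters (`rural_mean`, `rural_sd`, `rural_prob`, and referral
#'   counterparts).
#' @examples
#' covariate_spec("age", "continuous", mean = 55, sd = 15)
#' covariate_spec("sex", "binary", prob = 0.5)
#' @export
covariate_spec <- function(name, kind = c("continuous", "binary"),
                           mean = NULL, sd = NULL, prob = NULL,
                           rural = NULL, referral = NULL) {
  kind <- match.arg(kind)
  base <- if (kind == "continuous") {
    if (is.null(mean) || is.null(sd)) {
      abort("continuous covariates need `mean` and `sd`.")
    }
    if (sd < 0) abort("`sd` must be >= 0.")
    list(mean = mean, sd = sd, prob = NA_real_)
  } else {
    if (is.null(prob)) abort("binary covariates need `prob`.")
    .check_prob(prob, "prob")
    list(mean = NA_real_, sd = NA_real_, prob = prob)
  }
  arm_params <- function(override) {
    p <- modifyList(base, override %||% list())
    if (kind == "continuous" && p$sd < 0) abort("`sd` must be >= 0.")
    if (kind == "binary") .check_prob(p$prob, "prob")
    p
  }
  ru <- arm_params(rural)
  rf <- arm_params(referral)
  tibble(
    name = name, kind = kind,
    rural_mean = ru$mean, rural_sd = ru$sd, rural_prob = ru$prob,
    referral_mean = rf$mean, referral_sd = rf$sd, referral_prob = rf$prob
  )
}

#' Default covariate set for an index procedure
#'
#' Age, sex and income decile for every procedure; laparoscopy for hernia
#' repair and appendectomy; gravidity and emergency-versus-elective for
#' cesarean delivery. The cesarean set omits sex: that population is
#' all-female and a constant column would make the design rank-deficient.
#' Parameter values are package defaults chosen to be realistic for each
#' surgical population; because simulated covariates are null with respect to
#' the outcome, power results are insensitive to them.
#'
#' @param procedure One of `"hernia repair"`, `"appendectomy"`,
#'   `"colonoscopy"`, `"cesarean delivery"`.
#' @return A tibble of covariate specifications (see [covariate_spec()]).
#' @export
default_covariates <- function(procedure) {
  procedure <- match.arg(procedure, c(
    "hernia repair", "appendectomy", "colonoscopy", "cesarean delivery"
  ))
  age <- switch(procedure,
    "hernia repair"     = covariate_spec("age", "continuous", mean = 55, sd = 16),
    "appendectomy"      = covariate_spec("age", "continuous", mean = 38, sd = 18),
    "colonoscopy"       = covariate_spec("age", "continuous", mean = 60, sd = 12),
    "cesarean delivery" = covariate_spec("age", "continuous", mean = 31, sd = 5.5)
  )
  income <- covariate_spec("income_decile", "continuous", mean = 5.5, sd = 2.9)
  extra <- switch(procedure,
    "hernia repair" = bind_rows(
      covariate_spec("sex_female", "binary", prob = 0.25),
      covariate_spec("laparoscopy", "binary", prob = 0.4)
    ),
    "appendectomy" = bind_rows(
      covariate_spec("sex_female", "binary", prob = 0.5),
      covariate_spec("laparoscopy", "binary", prob = 0.8)
    ),
    "colonoscopy" = covariate_spec("sex_female", "binary", prob = 0.5),
    "cesarean delivery" = bind_rows(
      covariate_spec("gravidity", "continuous", mean = 2.4, sd = 1.4),
      covariate_spec("emergency", "binary", prob = 0.6)
    )
  )
  bind_rows(age, extra, income)
}

#' Construct a simulation scenario
#'
#' A scenario fixes everything the cohort simulator needs for one
#' risk-stratified population: the total number of visits, how many are
#' rural, the per-arm adverse-event proportions, and the covariate
#' distributions. Strata are cumulative in comorbidity level: `cl_max = 2`
#' means patients with comorbidity level 0, 1 or 2.
#'
#' @param procedure Index procedure label.
#' @param cl_max Highest comorbidity level included (0-4).
#' @param n_total Total visits available for the stratum.
#' @param n_rural Rural visits among `n_total`.
#' @param p_event_rural,p_event_referral Adverse-event proportions per arm.
#' @param covariates Tibble of covariate specs; defaults to
#'   [default_covariates()] for the procedure.
#' @return A one-row tibble with a `covariates` list-column.
#' @export
scenario_preset <- function(procedure, cl_max, n_total, n_rural,
                            p_event_rural, p_event_referral,
                            covariates = default_covariates(procedure)) {
  .check_count(n_total, "n_total")
  .check_count(n_rural, "n_rural")
  if (n_rural >= n_total) abort("`n_rural` must be smaller than `n_total`.")
  .check_prob(p_event_rural, "p_event_rural")
  .check_prob(p_event_referral, "p_event_referral")
  if (!cl_max %in% 0:4) abort("`cl_max` must be an integer in 0..4.")
  tibble(
    procedure = procedure,
    cl_max = as.integer(cl_max),
    n_total = as.integer(n_total),
    n_rural = as.integer(n_rural),
    rural_fraction = n_rural / n_total,
    p_event_rural = p_event_rural,
    p_event_referral = p_event_referral,
    covariates = list(covariates)
  )
}

#' Study scenarios for the four index procedures
#'
#' The 20 scenarios (4 index procedures x 5 cumulative comorbidity strata)
#' that define the simulation study: per stratum, the available number of
#' visits, the rural share, and the observed rural and referral
#' adverse-event proportions. These drive both the power engine and the
#' cohort simulator.
#'
#' @param procedure Optional filter: return only one procedure's strata.
#' @param cl_max Optional filter: return only one stratum.
#' @return A tibble with one row per scenario (see [scenario_preset()]).
#' @examples
#' table2_presets("hernia repair", cl_max = 4)
#' @export
table2_presets <- function(procedure = NULL, cl_max = NULL) {
  rows <- list(
    # procedure, cl_max, n_total, n_rural, p_rural, p_referral
    list("hernia repair", 0L, 7460L, 994L, 0.012, 0.017),
    list("hernia repair", 1L, 7634L, 998L, 0.012, 0.024),
    list("hernia repair", 2L, 7706L, 999L, 0.012, 0.029),
    list("hernia repair", 3L, 7753L, 999L, 0.012, 0.034),
    list("hernia repair", 4L, 7792L, 999L, 0.012, 0.038),
    list("appendectomy", 0L, 2392L, 134L, 0.030, 0.032),
    list("appendectomy", 1L, 2534L, 135L, 0.037, 0.063),
    list("appendectomy", 2L, 2587L, 135L, 0.037, 0.075),
    list("appendectomy", 3L, 2607L, 136L, 0.044, 0.081),
    list("appendectomy", 4L, 2613L, 136L, 0.044, 0.083),
    list("colonoscopy", 0L, 51319L, 10513L, 0.004, 0.005),
    list("colonoscopy", 1L, 51601L, 10535L, 0.005, 0.007),
    list("colonoscopy", 2L, 51780L, 10550L, 0.005, 0.009),
    list("colonoscopy", 3L, 51891L, 10558L, 0.005, 0.010),
    list("colonoscopy", 4L, 51968L, 10559L, 0.005, 0.012),
    list("cesarean delivery", 0L, 5183L, 852L, 0.012, 0.015),
    list("cesarean delivery", 1L, 5801L, 928L, 0.016, 0.020),
    list("cesarean delivery", 2L, 5953L, 937L, 0.018, 0.021),
    list("cesarean delivery", 3L, 5962L, 937L, 0.018, 0.021),
    list("cesarean delivery", 4L, 5972L, 937L, 0.018, 0.021)
  )
  out <- purrr::map_dfr(rows, function(r) {
    scenario_preset(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]])
  })
  if (!is.null(procedure)) {
    procedure <- match.arg(procedure, unique(out$procedure))
    out <- filter(out, .data$procedure == !!procedure)
  }
  if (!is.null(cl_max)) out <- filter(out, .data$cl_max == !!cl_max)
  out
}
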