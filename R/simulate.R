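#' Simulate a patient-visit cohort
#'
#' Draws a synthetic cohort with the structure the facility-comparison
#' analysis assumes: a fixed rural/referral split proportional to the
#' scenario's relative volumes, a Bernoulli adverse-event indicator per visit
#' with the arm's event proportion, and covariates drawn independently per
#' arm from their specified normal or Bernoulli distributions. Covariates
#' have no effect on the outcome (null covariates), so the facility effect
#' is the only signal in the data.
#'
#' The arm split is deterministic: `n_rural = round(rural_fraction * n)` and
#' `n_referral = n - n_rural`. A comorbidity-level column is drawn from a
#' fixed decreasing distribution over `0..cl_max` (most patients carry no
#' costed comorbidity); it is descriptive only and is never used as a model
#' term.
#'
#' @param preset A one-row scenario tibble (see [scenario_preset()],
#'   [table2_presets()]).
#' @param n Number of visits to simulate; defaults to the scenario's
#'   `n_total`.
#' @param seed Integer seed; the same seed and scenario reproduce the cohort
#'   exactly. The caller's RNG state is left untouched.
#' @return A tibble with columns `arm` (`"rural"`/`"referral"`), `cl`
#'   (comorbidity level), `event` (0/1) and one column per covariate.
#' @examples
#' preset <- table2_presets("hernia repair", cl_max = 4)
#' sim <- simulate_cohort(preset, n = 500, seed = 1)
#' dplyr::count(sim, arm, event)
#' @export
simulate_cohort <- function(preset, n = NULL, seed = 1L) {
  preset <- .as_preset_row(preset)
  n <- as.integer(n %||% preset$n_total)
  if (n < 2L) abort("`n` must be at least 2.")
  n_rural <- as.integer(round(preset$rural_fraction * n))
  n_referral <- n - n_rural
  if (n_rural < 1L || n_referral < 1L) {
    abort("degenerate design: `n` is too small to place a visit in each arm.")
  }
  covs <- preset$covariates[[1]]
  cl_weights <- c(0.55, 0.2, 0.12, 0.08, 0.05)[seq_len(preset$cl_max + 1L)]
  withr::with_seed(seed, {
    arm <- rep(c("rural", "referral"), c(n_rural, n_referral))
    event <- c(
      rbinom(n_rural, 1L, preset$p_event_rural),
      rbinom(n_referral, 1L, preset$p_event_referral)
    )
    cl <- sample(0:preset$cl_max, n, replace = TRUE, prob = cl_weights)
    out <- tibble(arm = arm, cl = cl, event = event)
    for (i in seq_len(nrow(covs))) {
      cv <- covs[i, ]
      draw <- function(m, s, p, k) {
        if (cv$kind == "continuous") rnorm(k, m, s) else rbinom(k, 1L, p)
      }
      out[[cv$name]] <- c(
        draw(cv$rural_mean, cv$rural_sd, cv$rural_prob, n_rural),
        draw(cv$referral_mean, cv$referral_sd, cv$referral_prob, n_referral)
      )
    }
    out
  })
}

# accept a one-row tibble or a (filtered) preset table with exactly one row
.as_preset_row <- function(preset) {
  if (!is.data.frame(preset) || nrow(preset) != 1L) {
    abort("`preset` must be a single scenario (a one-row tibble).")
  }
  needed <- c(
    "cl_max", "n_total", "rural_fraction",
    "p_event_rural", "p_event_referral", "covariates"
  )
  missing <- setdiff(needed, names(preset))
  if (length(missing)) {
    abort(paste0("`preset` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  preset
}
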