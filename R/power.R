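# Per-replication two-sided p-values for the facility effect under one or
# both engines, on identical simulated cohorts (paired design: every engine
# sees the same data within a replication). Returns one row per replication.
.power_pvalues <- function(preset, n, replications, seed,
                           engines = c("mle", "firth")) {
  preset <- .as_preset_row(preset)
  seeds <- .seed_stream(seed, replications)
  design <- NULL
  out <- vector("list", replications)
  for (i in seq_len(replications)) {
    cohort <- simulate_cohort(preset, n = n, seed = seeds[i])
    design <- design %||% .design_for_cohort(cohort)
    dd <- .build_design(cohort, design)
    j <- match(design$treatment, colnames(dd$X))
    row <- list(replication = i)
    if ("mle" %in% engines) {
      res <- tryCatch({
        fit <- suppressWarnings(fit_logistic(cohort, design))
        if (fit$separation || !fit$converged) {
          list(p = NA_real_, failed = TRUE)
        } else {
          z <- fit$coefficients[[design$treatment]] / fit$se[[design$treatment]]
          list(p = 2 * pnorm(-abs(z)), failed = FALSE)
        }
      }, error = function(e) list(p = NA_real_, failed = TRUE))
      row$p_mle <- res$p
      row$failed_mle <- res$failed
    }
    if ("firth" %in% engines) {
      res <- tryCatch({
        core <- .plrt_core(dd$X, dd$y, j, 0)
        list(p = pchisq(core$statistic, df = 1, lower.tail = FALSE),
             failed = FALSE)
      }, error = function(e) list(p = NA_real_, failed = TRUE))
      row$p_firth <- res$p
      row$failed_firth <- res$failed
    }
    out[[i]] <- tibble::as_tibble(row)
  }
  bind_rows(out)
}

.power_from_pvalues <- function(p, failed, alpha) {
  # failed fits count as non-rejections, never discarded
  reject <- !failed & !is.na(p) & p < alpha
  power <- mean(reject)
  list(power = power,
       mc_se = sqrt(power * (1 - power) / length(p)),
       failed = sum(failed))
}

#' Monte Carlo power of the facility-effect test
#'
#' Estimates the power to detect the rural-versus-referral difference in
#' adverse-event proportions encoded by a scenario: each replication
#' simulates a cohort, fits the chosen engine with the scenario's null
#' covariates as adjustment terms, and tests the treatment coefficient
#' against zero - a two-sided Wald test for the `"mle"` engine, a two-sided
#' penalized likelihood-ratio test for `"firth"`. Power is the fraction of
#' replications with p below `alpha`. Replications where the MLE fit fails
#' (separation) count as non-rejections and are reported in `failed_fits`.
#'
#' @param preset A one-row scenario tibble.
#' @param n Cohort size per replication; defaults to the scenario's
#'   `n_total`.
#' @param engine `"firth"` (default) or `"mle"`.
#' @param replications Number of Monte Carlo replications (default 1000).
#' @param alpha Two-sided test level (default 0.05).
#' @param seed Root seed; per-replication seeds are derived from it, so the
#'   same root seed reproduces the estimate exactly and both engines see
#'   identical cohorts.
#' @return A one-row tibble: `engine`, `n`, `replications`, `power`,
#'   `mc_se` (binomial Monte Carlo standard error), `alpha`, `failed_fits`.
#' @examples
#' preset <- table2_presets("hernia repair", cl_max = 4)
#' estimate_power(preset, engine = "firth", replications = 20, seed = 1)
#' @export
estimate_power <- function(preset, n = NULL, engine = c("firth", "mle"),
                           replications = 1000L, alpha = 0.05, seed = 1L) {
  engine <- match.arg(engine)
  preset <- .as_preset_row(preset)
  replications <- .check_count(replications, "replications")
  .check_prob(alpha, "alpha")
  n <- as.integer(n %||% preset$n_total)
  if (preset$p_event_rural == 0 && preset$p_event_referral == 0) {
    warn("degenerate scenario: both event proportions are 0; power is 0.")
    return(tibble(engine = engine, n = n, replications = replications,
                  power = 0, mc_se = 0, alpha = alpha,
                  failed_fits = 0L))
  }
  pv <- .power_pvalues(preset, n, replications, seed, engines = engine)
  res <- .power_from_pvalues(pv[[paste0("p_", engine)]],
                             pv[[paste0("failed_", engine)]], alpha)
  tibble(
    engine = engine, n = n, replications = replications,
    power = res$power, mc_se = res$mc_se, alpha = alpha,
    failed_fits = res$failed
  )
}

#' Power across a grid of sample sizes
#'
#' Convenience wrapper running [estimate_power()] over a vector of sample
#' sizes (optionally for both engines); the result has an [autoplot()]
#' method drawing the power curve with a Monte Carlo uncertainty ribbon.
#'
#' @inheritParams estimate_power
#' @param n_values Vector of cohort sizes.
#' @param engines Engines to run (default both).
#' @return A tibble of class `rni_power_curve`, one row per `n` x engine.
#' @export
power_curve <- function(preset, n_values, engines = c("mle", "firth"),
                        replications = 1000L, alpha = 0.05, seed = 1L) {
  engines <- match.arg(engines, several.ok = TRUE)
  rows <- purrr::map_dfr(n_values, function(nn) {
    pv <- .power_pvalues(preset, as.integer(nn), replications, seed, engines)
    purrr::map_dfr(engines, function(eng) {
      res <- .power_from_pvalues(pv[[paste0("p_", eng)]],
                                 pv[[paste0("failed_", eng)]], alpha)
      tibble(engine = eng, n = as.integer(nn), replications = replications,
             power = res$power, mc_se = res$mc_se, alpha = alpha,
             failed_fits = res$failed)
    })
  })
  class(rows) <- c("rni_power_curve", class(rows))
  rows
}

#' Minimum sample size reaching a target power
#'
#' Searches a sample-size grid for the smallest n at which the Monte Carlo
#' power of the facility-effect test reaches the target (0.8 by default):
#' a geometric coarse grid over `[grid_lo, grid_hi]` brackets the crossing,
#' then bisection narrows it to the stated resolution. The search assumes
#' power is monotone in n (true up to Monte Carlo noise whenever the arm
#' proportions differ); if an evaluation contradicts monotonicity beyond
#' noise a warning reports both brackets. When even `grid_hi` falls short
#' the result is the sentinel `above_grid = TRUE` with `n_min = Inf`,
#' reported as ">grid_hi".
#'
#' @inheritParams estimate_power
#' @param target_power Power to reach (default 0.8).
#' @param grid_lo,grid_hi Search bounds (defaults 1000 and 100,000).
#' @param resolution Granularity of the reported n (default 10).
#' @return A one-row tibble of class `rni_minn`: `engine`, `target_power`,
#'   `n_min` (`Inf` when above the grid), `above_grid`, grid metadata, and
#'   the evaluation `trace` as a list-column (n, power, mc_se per point).
#' @export
min_sample_size <- function(preset, engine = c("firth", "mle"),
                            target_power = 0.8, grid_lo = 1000L,
                            grid_hi = 100000L, resolution = 10L,
                            replications = 1000L, alpha = 0.05, seed = 1L) {
  engine <- match.arg(engine)
  preset <- .as_preset_row(preset)
  .check_prob(target_power, "target_power")
  grid_lo <- .check_count(grid_lo, "grid_lo", min = 2L)
  grid_hi <- .check_count(grid_hi, "grid_hi")
  resolution <- .check_count(resolution, "resolution")
  if (grid_lo >= grid_hi) abort("`grid_lo` must be below `grid_hi`.")

  trace <- list()
  eval_power <- function(nn) {
    est <- estimate_power(preset, n = nn, engine = engine,
                          replications = replications, alpha = alpha,
                          seed = seed)
    trace[[length(trace) + 1L]] <<- est
    est
  }

  # geometric coarse grid, snapped to the resolution
  coarse <- unique(pmin(grid_hi, pmax(grid_lo, as.integer(
    resolution * round(exp(seq(log(grid_lo), log(grid_hi), length.out = 8L)) /
                         resolution)
  ))))
  lo <- NA_integer_  # highest n seen below target
  hi <- NA_integer_  # lowest n seen at/above target
  for (nn in coarse) {
    est <- eval_power(nn)
    if (est$power >= target_power) {
      hi <- nn
      break
    }
    lo <- nn
  }
  if (is.na(hi)) {
    return(.minn_result(engine, target_power, Inf, TRUE, grid_lo, grid_hi,
                        resolution, trace))
  }
  if (is.na(lo)) {
    return(.minn_result(engine, target_power, hi, FALSE, grid_lo, grid_hi,
                        resolution, trace))
  }
  hi_est <- trace[[length(trace)]]
  while (hi - lo > resolution) {
    mid <- as.integer(resolution * round((lo + hi) / 2 / resolution))
    if (mid <= lo || mid >= hi) break
    est <- eval_power(mid)
    if (est$power >= target_power) {
      hi <- mid
      hi_est <- est
    } else {
      # monotonicity check against the accepted upper bracket
      pooled_se <- sqrt(est$mc_se^2 + hi_est$mc_se^2)
      if (est$power > hi_est$power + 3 * pooled_se) {
        warn(sprintf(
          "power non-monotone beyond Monte Carlo noise between n = %d (%.3f) and n = %d (%.3f).",
          mid, est$power, hi, hi_est$power
        ))
      }
      lo <- mid
    }
  }
  .minn_result(engine, target_power, hi, FALSE, grid_lo, grid_hi,
               resolution, trace)
}

.minn_result <- function(engine, target_power, n_min, above_grid,
                         grid_lo, grid_hi, resolution, trace) {
  out <- tibble(
    engine = engine, target_power = target_power,
    n_min = n_min, above_grid = above_grid,
    label = if (above_grid) paste0(">", format(grid_hi, scientific = FALSE))
            else format(n_min, scientific = FALSE),
    grid_lo = grid_lo, grid_hi = grid_hi, resolution = resolution,
    trace = list(bind_rows(trace))
  )
  class(out) <- c("rni_minn", class(out))
  out
}

#' Power summary table across scenarios
#'
#' Runs the available-data power estimate for every scenario in `presets`
#' under both engines (on identical cohorts per replication), and optionally
#' the minimum-sample-size search, yielding one row per scenario in the
#' layout of the study's summary table: scenario descriptors, per-engine
#' power at the available n, and per-engine minimum n for the target power.
#'
#' @param presets Tibble of scenarios (e.g. [table2_presets()]).
#' @param replications Replications for the available-n power estimates.
#' @param alpha Two-sided test level (default 0.05).
#' @param seed Root seed.
#' @param min_n Also run the minimum-sample-size search? Default `FALSE`
#'   (it dominates the runtime).
#' @param target_power,grid_lo,grid_hi,resolution,min_n_replications
#'   Search settings passed to [min_sample_size()] when `min_n = TRUE`.
#' @return A tibble with one row per scenario.
#' @export
run_power_table <- function(presets, replications = 1000L, alpha = 0.05,
                            seed = 1L, min_n = FALSE, target_power = 0.8,
                            grid_lo = 1000L, grid_hi = 100000L,
                            resolution = 10L,
                            min_n_replications = replications) {
  if (nrow(presets) == 0L) {
    return(tibble(
      procedure = character(), cl_max = integer(), n_total = integer(),
      n_rural = integer(), p_event_rural = numeric(),
      p_event_referral = numeric(),
      power_mle = numeric(), mc_se_mle = numeric(), failed_mle = integer(),
      power_firth = numeric(), mc_se_firth = numeric(),
      min_n_mle = character(), min_n_firth = character()
    ))
  }
  purrr::map_dfr(seq_len(nrow(presets)), function(i) {
    preset <- presets[i, ]
    pv <- .power_pvalues(preset, preset$n_total, replications, seed,
                         engines = c("mle", "firth"))
    m <- .power_from_pvalues(pv$p_mle, pv$failed_mle, alpha)
    f <- .power_from_pvalues(pv$p_firth, pv$failed_firth, alpha)
    row <- tibble(
      procedure = preset$procedure, cl_max = preset$cl_max,
      n_total = preset$n_total, n_rural = preset$n_rural,
      p_event_rural = preset$p_event_rural,
      p_event_referral = preset$p_event_referral,
      power_mle = m$power, mc_se_mle = m$mc_se, failed_mle = m$failed,
      power_firth = f$power, mc_se_firth = f$mc_se,
      min_n_mle = NA_character_, min_n_firth = NA_character_
    )
    if (min_n) {
      for (eng in c("mle", "firth")) {
        mn <- min_sample_size(
          preset, engine = eng, target_power = target_power,
          grid_lo = grid_lo, grid_hi = grid_hi, resolution = resolution,
          replications = min_n_replications, alpha = alpha, seed = seed
        )
        row[[paste0("min_n_", eng)]] <- mn$label
      }
    }
    row
  })
}
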