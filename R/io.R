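#' Read and write cohort tables
#'
#' The on-disk cohort format is a plain CSV with the documented header:
#' `arm` (`rural`/`referral`), `cl` (comorbidity level 0-4), `event` (0/1),
#' plus any covariate columns. `read_cohort_csv()` validates the schema and
#' reports row counts and per-column missingness; `write_cohort_csv()` is
#' the exact inverse, so a write-then-read round-trips the table.
#'
#' @param path File path.
#' @param quiet Suppress the validation summary? Default `FALSE`.
#' @return `read_cohort_csv()`: the validated cohort tibble (with the
#'   validation report in attribute `"validation"`); `write_cohort_csv()`:
#'   `path`, invisibly.
#' @export
read_cohort_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("arm", "cl", "event")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(paste0("cohort file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_arm <- which(!data$arm %in% c("rural", "referral"))
  if (length(bad_arm)) {
    abort(sprintf("`arm` must be rural/referral; offending row(s): %s",
                  paste(utils::head(bad_arm, 5), collapse = ", ")))
  }
  bad_event <- which(!data$event %in% c(0, 1))
  if (length(bad_event)) {
    abort(sprintf("`event` must be 0/1; offending row(s): %s",
                  paste(utils::head(bad_event, 5), collapse = ", ")))
  }
  bad_cl <- which(!data$cl %in% 0:4)
  if (length(bad_cl)) {
    abort(sprintf("`cl` must be an integer 0-4; offending row(s): %s",
                  paste(utils::head(bad_cl, 5), collapse = ", ")))
  }
  validation <- list(
    rows = nrow(data),
    columns = names(data),
    missing = purrr::map_int(data, ~ sum(is.na(.x)))
  )
  if (!quiet) {
    inform(sprintf(
      "cohort: %d rows, %d columns; %d missing value(s).",
      validation$rows, length(validation$columns), sum(validation$missing)
    ))
  }
  attr(data, "validation") <- validation
  data
}

#' @rdname read_cohort_csv
#' @param data Cohort tibble.
#' @export
write_cohort_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read coded hospital visits
#'
#' Visits come as CSV with `patient_id`, `visit_date` (ISO-8601) and
#' semicolon-separated `diagnosis_codes` / `intervention_codes` columns, the
#' layout [detect_events()] consumes.
#'
#' @param path File path.
#' @return A tibble of coded visits.
#' @export
read_visits_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("patient_id", "visit_date")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("visits file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  .parse_dates(data$visit_date, path)  # fail fast on bad dates
  data
}

#' Read adverse-event code sets
#'
#' Code sets map an event name to a vector of ICD-10-CA / CCI style code
#' prefixes, stored as YAML or JSON (by file extension).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A named list of character vectors.
#' @export
read_code_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  sets <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    abort("code sets must be a .yaml/.yml or .json file.")
  )
  if (!is.list(sets) || is.null(names(sets))) {
    abort("code sets must be a named mapping: event name -> list of codes.")
  }
  purrr::map(sets, as.character)
}

#' Run a reproducible analysis command
#'
#' Programmatic entry point behind the command-line interface: executes one
#' named subcommand from a configuration list (typically read from a YAML
#' file via [read_run_config()], with flags overriding file values), writes
#' its outputs (CSV/JSON) next to `config$out`, and logs the seed and
#' parameters so any run can be reproduced exactly from its log.
#'
#' Subcommands: `"simulate"` (scenario -> cohort CSV), `"fit"` (cohort CSV ->
#' fit JSON), `"power"`, `"min_n"`, `"table2"` (power table CSV over the
#' bundled scenarios), `"ni"` (noninferiority on counts or a cohort),
#' `"evalue"`, `"stratify"` (strata table CSV).
#'
#' @param config Named list; `command` selects the subcommand and the other
#'   entries supply its parameters (see the CLI script in
#'   `system.file("cli", "ruralni.R", package = "ruralni")`).
#' @return A list of output file paths, invisibly.
#' @export
run_command <- function(config) {
  cmd <- config$command %||% abort("`config$command` is required.")
  out <- config$out %||% abort("`config$out` (output path stem) is required.")
  seed <- as.integer(config$seed %||% 1L)
  alpha <- as.numeric(config$alpha %||% 0.05)
  reps <- as.integer(config$replications %||% 1000L)
  engine <- config$engine %||% "firth"
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) inform(sprintf(...))
  log_line("ruralni %s | command=%s seed=%d", .pkg_version(), cmd, seed)

  preset_from <- function() {
    if (!is.null(config$procedure)) {
      table2_presets(config$procedure, cl_max = as.integer(config$cl_max %||% 4L))
    } else {
      abort("this command needs `procedure` (and optionally `cl_max`).")
    }
  }
  artifacts <- switch(cmd,
    simulate = {
      preset <- preset_from()
      cohort <- simulate_cohort(preset, n = config$n %||% NULL, seed = seed)
      path <- paste0(out, "_cohort.csv")
      write_cohort_csv(cohort, path)
      log_line("wrote %s (%d rows)", path, nrow(cohort))
      list(cohort = path)
    },
    fit = {
      cohort <- read_cohort_csv(config$cohort, quiet = TRUE)
      design <- .design_from_config(config, cohort)
      fit <- if (engine == "firth") fit_firth(cohort, design)
             else fit_logistic(cohort, design)
      if (fit$separation) log_line("separation detected; see fit JSON.")
      path <- paste0(out, "_fit.json")
      jsonlite::write_json(
        list(
          engine = fit$engine,
          coefficients = as.list(fit$coefficients),
          std_errors = as.list(fit$se),
          loglik = fit$loglik,
          convergence = list(
            converged = fit$converged, iterations = fit$iterations,
            separation = fit$separation
          )
        ),
        path, auto_unbox = TRUE, digits = NA
      )
      log_line("wrote %s", path)
      list(fit = path)
    },
    power = {
      preset <- preset_from()
      est <- estimate_power(preset, n = config$n %||% NULL, engine = engine,
                            replications = reps, alpha = alpha, seed = seed)
      path <- paste0(out, "_power.json")
      jsonlite::write_json(as.list(est), path, auto_unbox = TRUE, digits = NA)
      log_line("power = %.4f (MC SE %.4f)", est$power, est$mc_se)
      list(power = path)
    },
    min_n = {
      preset <- preset_from()
      mn <- min_sample_size(
        preset, engine = engine,
        target_power = as.numeric(config$target_power %||% 0.8),
        grid_lo = as.integer(config$grid_lo %||% 1000L),
        grid_hi = as.integer(config$grid_hi %||% 100000L),
        resolution = as.integer(config$resolution %||% 10L),
        replications = reps, alpha = alpha, seed = seed
      )
      path <- paste0(out, "_min_n.json")
      jsonlite::write_json(
        as.list(select(mn, -"trace")), path, auto_unbox = TRUE, digits = NA
      )
      readr::write_csv(mn$trace[[1]], paste0(out, "_min_n_trace.csv"),
                       progress = FALSE)
      log_line("minimum n = %s", mn$label)
      list(min_n = path, trace = paste0(out, "_min_n_trace.csv"))
    },
    table2 = {
      tbl <- run_power_table(table2_presets(), replications = reps,
                             alpha = alpha, seed = seed)
      path <- paste0(out, "_power_table.csv")
      readr::write_csv(tbl, path, progress = FALSE)
      log_line("wrote %s (%d rows)", path, nrow(tbl))
      list(table = path)
    },
    ni = {
      margin <- if (!is.null(config$delta)) {
        ni_margin(as.numeric(config$delta),
                  tau_c = config$tau_c %||% NULL)
      } else {
        margin_from_ci(
          as.numeric(config$tau_t), as.numeric(config$tau_c),
          as.integer(config$n_t), as.integer(config$n_c)
        )
      }
      res <- if (!is.null(config$cohort)) {
        cohort <- read_cohort_csv(config$cohort, quiet = TRUE)
        test_or_ni(cohort, .design_from_config(config, cohort),
                   margin = margin, engine = engine,
                   alpha = as.numeric(config$alpha %||% 0.025))
      } else {
        test_proportions_ni(
          as.integer(config$events_t), as.integer(config$n_t),
          as.integer(config$events_c), as.integer(config$n_c),
          margin = margin, alpha = as.numeric(config$alpha %||% 0.025)
        )
      }
      path <- paste0(out, "_ni.json")
      jsonlite::write_json(as.list(tidy(res)), path, auto_unbox = TRUE,
                           digits = NA)
      log_line("one-sided p = %.4g -> %s", res$p_value,
               if (res$noninferior) "noninferior" else "not shown")
      list(ni = path)
    },
    evalue = {
      ev <- e_value(as.numeric(config$or),
                    ci_lo = config$ci_lo %||% NULL,
                    ci_hi = config$ci_hi %||% NULL)
      path <- paste0(out, "_evalue.json")
      jsonlite::write_json(as.list(ev), path, auto_unbox = TRUE, digits = NA)
      log_line("E-value = %.4f", ev$e_value_point)
      list(evalue = path)
    },
    stratify = {
      cohort <- read_cohort_csv(config$cohort, quiet = TRUE)
      tbl <- strata_table(cohort)
      path <- paste0(out, "_strata.csv")
      readr::write_csv(tbl, path, progress = FALSE)
      log_line("wrote %s", path)
      list(strata = path)
    },
    abort(sprintf("unknown command `%s`.", cmd))
  )
  invisible(artifacts)
}

#' @rdname run_command
#' @param path YAML configuration file.
#' @param overrides Named list of values overriding the file's.
#' @export
read_run_config <- function(path, overrides = list()) {
  config <- if (is.null(path)) list() else yaml::read_yaml(path)
  modifyList(config, overrides[!purrr::map_lgl(overrides, is.null)])
}

.design_from_config <- function(config, cohort) {
  design_spec(
    outcome = config$outcome %||% "event",
    treatment = config$treatment %||% "arm",
    covariates = config$covariates %||%
      setdiff(names(cohort), c("arm", "cl", "event", "patient_id",
                               "visit_date"))
  )
}

.pkg_version <- function() {
  as.character(utils::packageVersion("ruralni"))
}
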