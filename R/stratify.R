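#' Cumulative comorbidity-level risk strata
#'
#' Splits a cohort into the five nested risk strata the stratified analysis
#' runs on: stratum k contains every visit with comorbidity level at most k,
#' so stratum 0 is the lowest-risk population and stratum 4 is the full
#' cohort. Stratifying (rather than adjusting for comorbidity level in the
#' model) avoids the inflated outcome-confounder correlation that arises
#' because the comorbidity grouping is itself built from coded diagnoses.
#'
#' @param data Cohort tibble with a comorbidity-level column.
#' @param cl_col Name of that column (default `"cl"`), integer values 0-4.
#' @return A named list of five tibbles (`"0"` ... `"4"`), nested subsets of
#'   `data`.
#' @export
cumulative_strata <- function(data, cl_col = "cl") {
  if (!cl_col %in% names(data)) {
    abort(sprintf("column `%s` not found.", cl_col))
  }
  cl <- data[[cl_col]]
  bad <- which(!cl %in% 0:4)
  if (length(bad)) {
    abort(sprintf(
      "comorbidity level out of range 0-4 in row(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  stats::setNames(
    purrr::map(0:4, function(k) data[cl <= k, , drop = FALSE]),
    as.character(0:4)
  )
}

#' Per-arm descriptive profile of a risk stratum
#'
#' Sample characteristics per facility arm for one stratum: visit counts,
#' combined adverse-event proportion, mean and standard deviation of each
#' continuous covariate, proportion for each binary covariate, and - when
#' individual adverse-event indicator columns are present - the per-event
#' proportions per arm. Reporting the individual event proportions alongside
#' the combined outcome shows what the combined comparison is actually made
#' of, and how stratification shifts each event's volume.
#'
#' @param data One stratum's cohort tibble (see [cumulative_strata()]).
#' @param covariates Covariate columns to profile; defaults to every numeric
#'   column other than `cl`, `event` and event indicators.
#' @param event_cols Individual event indicator columns; defaults to columns
#'   starting with `"event_"`.
#' @return A list of class `rni_profile`: `$arms` (n, events, event
#'   proportion per arm), `$covariates` (long tibble of per-arm summaries),
#'   `$events` (per-arm individual event proportions, possibly empty), and
#'   `$missing_arm` naming an absent arm (with a warning) or `NULL`.
#' @export
stratum_profile <- function(data, covariates = NULL, event_cols = NULL) {
  if (nrow(data) == 0L) abort("empty stratum.")
  if (!all(c("arm", "event") %in% names(data))) {
    abort("`data` needs `arm` and `event` columns.")
  }
  event_cols <- event_cols %||% grep("^event_", names(data), value = TRUE)
  covariates <- covariates %||% setdiff(
    names(data)[purrr::map_lgl(data, is.numeric)],
    c("cl", "event", event_cols)
  )
  arms_present <- unique(data$arm)
  missing_arm <- setdiff(c("rural", "referral"), arms_present)
  if (length(missing_arm)) {
    warn(paste0("arm(s) absent from the stratum: ",
                paste(missing_arm, collapse = ", ")))
  } else {
    missing_arm <- NULL
  }
  arms <- data %>%
    group_by(.data$arm) %>%
    summarise(
      n = dplyr::n(),
      events = sum(.data$event),
      p_event = mean(.data$event),
      .groups = "drop"
    )
  cov_tbl <- purrr::map_dfr(covariates, function(cn) {
    data %>%
      group_by(.data$arm) %>%
      summarise(
        covariate = cn,
        mean = mean(.data[[cn]]),
        sd = stats::sd(.data[[cn]]),
        proportion = if (all(.data[[cn]] %in% c(0, 1))) {
          mean(.data[[cn]])
        } else {
          NA_real_
        },
        .groups = "drop"
      )
  })
  ev_tbl <- purrr::map_dfr(event_cols, function(cn) {
    data %>%
      group_by(.data$arm) %>%
      summarise(event = cn, proportion = mean(.data[[cn]]), .groups = "drop")
  })
  structure(
    list(arms = arms, covariates = cov_tbl, events = ev_tbl,
         missing_arm = missing_arm),
    class = "rni_profile"
  )
}

#' @export
print.rni_profile <- function(x, ...) {
  cat("<stratum profile>\n")
  print(x$arms, ...)
  if (nrow(x$covariates)) {
    cat("covariates:\n")
    print(x$covariates, ...)
  }
  if (nrow(x$events)) {
    cat("individual events:\n")
    print(x$events, ...)
  }
  if (!is.null(x$missing_arm)) {
    cat("missing arm:", paste(x$missing_arm, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Descriptive table across all risk strata
#'
#' One row per cumulative stratum with the headline descriptors: total
#' visits, rural visits and fraction, and the per-arm combined adverse-event
#' proportions - the layout of a stratified study's first summary columns.
#'
#' @inheritParams cumulative_strata
#' @return A tibble with one row per stratum (cl_max 0-4).
#' @export
strata_table <- function(data, cl_col = "cl") {
  strata <- cumulative_strata(data, cl_col)
  purrr::map_dfr(names(strata), function(k) {
    s <- strata[[k]]
    tibble(
      cl_max = as.integer(k),
      n_total = nrow(s),
      n_rural = sum(s$arm == "rural"),
      rural_fraction = if (nrow(s)) mean(s$arm == "rural") else NA_real_,
      p_event_rural = mean(s$event[s$arm == "rural"]),
      p_event_referral = mean(s$event[s$arm == "referral"])
    )
  })
}
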