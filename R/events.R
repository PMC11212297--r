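#' Derive adverse-event indicators from coded visits
#'
#' Flags, for each index procedure visit, whether any hospital visit of the
#' same patient within a fixed day window carries a diagnosis or intervention
#' code belonging to a named adverse-event code set. The window is inclusive
#' at both ends: a visit on the index day (day 0) and a visit exactly
#' `window_days` after both count; day `window_days + 1` does not. Codes are
#' matched by exact prefix, so a set entry `"T81"` matches visit codes
#' `"T810"` and `"T8112"` (ICD-10-CA / CCI style).
#'
#' @param index_visits Tibble of index procedures: columns `patient_id`,
#'   `visit_date`, and optionally code columns as in `all_visits`.
#' @param all_visits Tibble of all hospital visits: `patient_id`,
#'   `visit_date`, plus `diagnosis_codes` and/or `intervention_codes`, each
#'   either a list-column of character vectors or a semicolon-separated
#'   string column.
#' @param code_sets Named list: event name -> character vector of code
#'   prefixes.
#' @param window_days Length of the follow-up window in days (default 30).
#' @param include_index_day Should codes on the index visit itself count?
#'   Default `TRUE`; set `FALSE` to start the window the day after the
#'   procedure.
#' @return `index_visits` with one 0/1 indicator column per event name.
#' @examples
#' idx <- tibble::tibble(patient_id = "p1", visit_date = "2020-01-01")
#' vis <- tibble::tibble(
#'   patient_id = "p1", visit_date = "2020-01-20",
#'   diagnosis_codes = "T810"
#' )
#' detect_events(idx, vis, list(hemorrhage = "T81"))
#' @export
detect_events <- function(index_visits, all_visits, code_sets,
                          window_days = 30L, include_index_day = TRUE) {
  if (!is.list(code_sets) || is.null(names(code_sets)) ||
      any(!nzchar(names(code_sets)))) {
    abort("`code_sets` must be a named list of code-prefix vectors.")
  }
  if (window_days < 0) abort("`window_days` must be >= 0.")
  idx_date <- .parse_dates(index_visits$visit_date, "index_visits")
  all_date <- .parse_dates(all_visits$visit_date, "all_visits")

  unknown <- setdiff(all_visits$patient_id, index_visits$patient_id)
  if (length(unknown)) {
    warn(sprintf(
      "%d visit(s) belong to patient id(s) absent from `index_visits`; ignored.",
      sum(all_visits$patient_id %in% unknown)
    ))
  }

  visit_codes <- .collect_codes(all_visits)
  out <- index_visits
  lo_offset <- if (include_index_day) 0L else 1L
  for (ev in names(code_sets)) {
    prefixes <- as.character(code_sets[[ev]])
    hit_visit <- purrr::map_lgl(visit_codes, function(codes) {
      length(codes) > 0L &&
        any(purrr::map_lgl(prefixes, function(p) any(startsWith(codes, p))))
    })
    ind <- integer(nrow(index_visits))
    for (i in seq_len(nrow(index_visits))) {
      in_window <- all_visits$patient_id == index_visits$patient_id[i] &
        all_date >= idx_date[i] + lo_offset &
        all_date <= idx_date[i] + window_days
      ind[i] <- as.integer(any(hit_visit & in_window))
    }
    out[[ev]] <- ind
  }
  out
}

.parse_dates <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  parsed <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    abort(sprintf(
      "unparseable visit_date in `%s` (expected ISO-8601, e.g. 2020-01-31): %s",
      what, paste(utils::head(x[is.na(parsed)], 3), collapse = ", ")
    ))
  }
  parsed
}

# one character vector of codes per visit row, from list-columns or
# semicolon-separated strings
.collect_codes <- function(visits) {
  cols <- intersect(c("diagnosis_codes", "intervention_codes"), names(visits))
  if (!length(cols)) {
    abort("`all_visits` needs a `diagnosis_codes` or `intervention_codes` column.")
  }
  per_col <- purrr::map(cols, function(cn) {
    col <- visits[[cn]]
    if (is.list(col)) {
      purrr::map(col, function(v) as.character(v[!is.na(v)]))
    } else {
      purrr::map(strsplit(ifelse(is.na(col), "", as.character(col)), ";"),
                 function(v) trimws(v[nzchar(trimws(v))]))
    }
  })
  purrr::pmap(per_col, c)
}

#' Combine individual adverse-event indicators
#'
#' Row-wise logical OR of a set of 0/1 indicator columns into a single
#' combined adverse-event indicator: the analysis outcome is "any adverse
#' event within the window". Combining events is what makes rare-event
#' comparisons feasible, at the price of ignoring relative severity - always
#' report the individual proportions alongside (see [stratum_profile()]).
#'
#' @param data Tibble containing the indicator columns.
#' @param columns Character vector of indicator column names; defaults to
#'   every column except `patient_id`/`visit_date`/`arm`/`cl` that holds
#'   only 0/1 values.
#' @param name Name of the combined column added to `data` (default
#'   `"event"`).
#' @return `data` with the combined 0/1 indicator appended.
#' @export
combine_events <- function(data, columns = NULL, name = "event") {
  if (is.null(columns)) {
    candidates <- setdiff(
      names(data), c("patient_id", "visit_date", "arm", "cl", name)
    )
    columns <- candidates[purrr::map_lgl(data[candidates], function(x) {
      is.numeric(x) && all(x %in% c(0, 1))
    })]
  }
  if (!length(columns)) abort("no indicator columns to combine.")
  missing <- setdiff(columns, names(data))
  if (length(missing)) {
    abort(paste0("unknown indicator column(s): ", paste(missing, collapse = ", ")))
  }
  mat <- as.matrix(data[columns])
  if (!all(mat %in% c(0, 1))) abort("indicator columns must be 0/1.")
  data[[name]] <- as.integer(rowSums(mat) > 0)
  data
}
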