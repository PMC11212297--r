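#' Specify a facility-effect regression design
#'
#' Names the outcome, the treatment (arm) indicator whose coefficient is the
#' adjusted log odds ratio, and the adjustment covariates. The treatment
#' column may be numeric 0/1 or the labels `"rural"`/`"referral"` (rural
#' codes to 1, so the coefficient is the log odds of an adverse event at a
#' rural versus a referral facility).
#'
#' @param outcome Binary outcome column name (default `"event"`).
#' @param treatment Arm indicator column name (default `"arm"`); `NULL` for
#'   an intercept-only or covariates-only model.
#' @param covariates Character vector of adjustment covariate names.
#' @param intercept Include an intercept? Default `TRUE`.
#' @return An object of class `rni_design`.
#' @export
design_spec <- function(outcome = "event", treatment = "arm",
                        covariates = character(), intercept = TRUE) {
  cols <- c(outcome, treatment, covariates)
  if (anyDuplicated(cols)) abort("design columns must be distinct.")
  if (is.null(treatment) && !length(covariates) && !isTRUE(intercept)) {
    abort("the design needs at least one term.")
  }
  structure(
    list(outcome = outcome, treatment = treatment,
         covariates = as.character(covariates), intercept = isTRUE(intercept)),
    class = "rni_design"
  )
}

# default design for a simulated cohort: event ~ arm + all covariate columns
.design_for_cohort <- function(cohort) {
  design_spec(
    outcome = "event", treatment = "arm",
    covariates = setdiff(names(cohort), c("arm", "cl", "event",
                                          "patient_id", "visit_date"))
  )
}

# build y and the model matrix; treatment column is second when intercept on,
# first otherwise
.build_design <- function(data, design) {
  for (col in c(design$outcome, design$treatment, design$covariates)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found.", col))
  }
  y <- data[[design$outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y) || !all(y %in% c(0, 1))) {
    abort(sprintf("outcome `%s` must be binary 0/1.", design$outcome))
  }
  tr <- NULL
  if (!is.null(design$treatment)) {
    tr <- data[[design$treatment]]
    if (is.factor(tr)) tr <- as.character(tr)
    if (is.character(tr)) {
      lev <- unique(tr)
      if (all(lev %in% c("rural", "referral"))) {
        tr <- as.integer(tr == "rural")
      } else if (length(lev) == 2L) {
        tr <- as.integer(tr == sort(lev)[2L])
      } else {
        abort(sprintf("treatment `%s` must be binary.", design$treatment))
      }
    }
    if (!all(tr %in% c(0, 1))) {
      abort(sprintf("treatment `%s` must be binary.", design$treatment))
    }
  }
  covs <- purrr::map(design$covariates, function(cn) {
    v <- data[[cn]]
    if (is.logical(v)) v <- as.integer(v)
    if (!is.numeric(v)) abort(sprintf("covariate `%s` must be numeric.", cn))
    v
  })
  X <- do.call(cbind, c(
    if (design$intercept) list(`(Intercept)` = rep(1, nrow(data))),
    if (!is.null(tr)) stats::setNames(list(as.numeric(tr)), design$treatment),
    stats::setNames(covs, design$covariates)
  ))
  const <- which(apply(X, 2L, function(col) length(unique(col)) == 1L))
  const <- setdiff(colnames(X)[const], "(Intercept)")
  if (length(const)) {
    abort(paste0("constant column(s) in the design: ",
                 paste(const, collapse = ", ")))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    abort(paste0("design matrix is rank-deficient; dependent column(s): ",
                 paste(dep, collapse = ", ")))
  }
  list(X = X, y = as.numeric(y))
}

# Newton iteration on the Firth-modified score with step-halving.
# `fixed`/`fixed_value` hold named coefficients at a constrained value while
# the penalty keeps using the full-design information (constrained fits for
# the penalized LRT).
.firth_newton <- function(X, y, fixed = integer(0), fixed_value = numeric(0),
                          beta0 = NULL, tol = 1e-8, max_iter = 100L) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed)
  beta <- beta0 %||% numeric(p)
  beta[fixed] <- fixed_value
  state <- function(beta) {
    eta <- drop(X %*% beta)
    pi <- plogis(eta)
    w <- pi * (1 - pi)
    R <- tryCatch(chol(crossprod(X * sqrt(pmax(w, 1e-300)))),
                  error = function(e) NULL)
    if (is.null(R)) return(list(pll = -Inf))
    ll <- sum(y * eta - .log1pexp(eta))
    list(pll = ll + sum(log(diag(R))), pi = pi, w = w, R = R)
  }
  st <- state(beta)
  if (!is.finite(st$pll)) abort("Firth fit failed at the starting value.")
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    Iinv <- chol2inv(st$R)
    h <- rowSums((X %*% Iinv) * X) * st$w
    U <- drop(crossprod(X, y - st$pi + h * (0.5 - st$pi)))
    if (max(abs(U[free])) < tol) {
      converged <- TRUE
      break
    }
    delta <- numeric(p)
    Xf <- X[, free, drop = FALSE]
    delta[free] <- tryCatch(
      solve(crossprod(Xf * sqrt(st$w)), U[free]),
      error = function(e) abort("Firth Newton step failed: singular information.")
    )
    step <- 1
    for (k in 1:25) {
      cand <- beta + step * delta
      st_new <- state(cand)
      if (is.finite(st_new$pll) && st_new$pll >= st$pll - 1e-12) break
      step <- step / 2
    }
    moved <- max(abs(step * delta[free]))
    beta <- cand
    st <- st_new
    if (moved < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  vcov <- chol2inv(st$R)
  list(
    beta = stats::setNames(beta, colnames(X)),
    se = stats::setNames(sqrt(diag(vcov)), colnames(X)),
    vcov = vcov, loglik = st$pll, iterations = iter, converged = converged
  )
}

.new_fit <- function(engine, est, design, n, separation = FALSE) {
  structure(
    list(
      engine = engine,
      coefficients = est$beta, se = est$se, vcov = est$vcov,
      loglik = est$loglik, converged = est$converged,
      iterations = est$iterations, separation = separation,
      design = design, n = n
    ),
    class = "rni_fit"
  )
}

#' Firth penalized logistic regression
#'
#' Fits a binary-outcome regression by maximizing the Jeffreys-penalized
#' log-likelihood `l*(b) = l(b) + log det I(b) / 2`, the penalty that keeps
#' estimates finite and bias-reduced when events are rare and the data are
#' (quasi-)separated. The optimizer is Newton iteration on the
#' Firth-modified score with hat-diagonal correction and step-halving;
#' convergence when the largest modified-score component or coefficient
#' change drops below `1e-8` (at most 100 iterations).
#'
#' @param data Cohort tibble (e.g. from [simulate_cohort()]).
#' @param design An [design_spec()]; defaults to `event ~ arm + ` every other
#'   numeric column.
#' @return An `rni_fit` object: coefficients and standard errors on the
#'   log-odds scale, the penalized log-likelihood, and convergence
#'   diagnostics. Use [tidy()]/[glance()] for tibble views.
#' @examples
#' # complete separation: the MLE diverges, the Firth estimate is finite
#' d <- tibble::tibble(event = c(0, 0, 1, 1), arm = c(0, 0, 1, 1))
#' fit_firth(d, design_spec(covariates = character()))
#' @export
fit_firth <- function(data, design = NULL) {
  design <- design %||% .design_for_cohort(data)
  if (nrow(data) < 2L) abort("need at least 2 rows.")
  dd <- .build_design(data, design)
  est <- .firth_newton(dd$X, dd$y)
  .new_fit("firth", est, design, nrow(data))
}

#' Maximum-likelihood logistic regression with separation diagnostics
#'
#' Standard logistic regression by iteratively reweighted least squares
#' (through [stats::glm.fit()]), wrapped with the separation handling that
#' rare-event facility comparisons need: when the likelihood has no finite
#' maximum (complete or quasi-separation), the fit is flagged
#' (`separation = TRUE`, `converged = FALSE`) and the last-iterate
#' coefficients are returned with a warning rather than presented as valid
#' estimates. Separation is detected from fitted probabilities pinned at 0
#' or 1, IRLS non-convergence, or a diverging coefficient norm.
#'
#' @inheritParams fit_firth
#' @return An `rni_fit` object (see [fit_firth()]); `loglik` is the
#'   unpenalized log-likelihood.
#' @export
fit_logistic <- function(data, design = NULL) {
  design <- design %||% .design_for_cohort(data)
  if (nrow(data) < 2L) abort("need at least 2 rows.")
  dd <- .build_design(data, design)
  if (length(unique(dd$y)) < 2L) {
    abort("outcome has a single class: the unpenalized likelihood is unbounded.")
  }
  fit <- withCallingHandlers(
    glm.fit(dd$X, dd$y, family = binomial()),
    warning = function(w) invokeRestart("muffleWarning")
  )
  beta <- stats::setNames(fit$coefficients, colnames(dd$X))
  eta <- drop(dd$X %*% beta)
  pi <- plogis(eta)
  w <- pi * (1 - pi)
  R <- tryCatch(chol(crossprod(dd$X * sqrt(pmax(w, 1e-300)))),
                error = function(e) NULL)
  vcov <- if (is.null(R)) {
    matrix(NA_real_, ncol(dd$X), ncol(dd$X))
  } else {
    chol2inv(R)
  }
  separation <- !fit$converged ||
    any(pi < 1e-10 | pi > 1 - 1e-10) ||
    sqrt(sum(beta^2)) > 1e3 ||
    is.null(R)
  if (separation) {
    warn(paste(
      "possible complete or quasi-separation: maximum-likelihood estimates",
      "are unreliable; coefficients reported at the last iterate.",
      "Consider fit_firth()."
    ))
  }
  est <- list(
    beta = beta,
    se = stats::setNames(sqrt(diag(vcov)), colnames(dd$X)),
    vcov = vcov,
    loglik = sum(dd$y * eta - .log1pexp(eta)),
    iterations = fit$iter,
    converged = fit$converged && !separation
  )
  .new_fit("mle", est, design, nrow(data), separation = separation)
}

#' @export
print.rni_fit <- function(x, ...) {
  cat(sprintf(
    "<%s logistic fit>  n = %d, %s in %d iteration(s)%s\n",
    if (x$engine == "firth") "Firth penalized" else "maximum-likelihood",
    x$n, if (x$converged) "converged" else "NOT converged", x$iterations,
    if (x$separation) ", separation detected" else ""
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a facility-effect fit
#'
#' @param x An `rni_fit` from [fit_firth()] or [fit_logistic()].
#' @param conf_level Wald confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with one row per model term: estimate, standard error,
#'   Wald statistic and two-sided p-value, confidence bounds, and the odds
#'   ratio.
#' @exportS3Method generics::tidy
tidy.rni_fit <- function(x, conf_level = 0.95, ...) {
  z <- x$coefficients / x$se
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    conf.low = unname(x$coefficients - q * x$se),
    conf.high = unname(x$coefficients + q * x$se),
    odds.ratio = unname(exp(x$coefficients))
  )
}

#' Fit-level summary of a facility-effect model
#'
#' @param x An `rni_fit`.
#' @param ... Unused.
#' @return A one-row tibble: engine, (penalized) log-likelihood, sample
#'   size, convergence and separation flags, iteration count.
#' @exportS3Method generics::glance
glance.rni_fit <- function(x, ...) {
  tibble(
    engine = x$engine, logLik = x$loglik, nobs = x$n,
    converged = x$converged, separation = x$separation,
    iterations = x$iterations
  )
}
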