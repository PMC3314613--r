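#' Baseline survival values
#'
#' A baseline survival is the survival probability at the prediction horizon
#' for a person at the reference (mean) risk profile. `baseline_survival()`
#' builds one; `horizon_baseline_survival()` rescales one horizon to another
#' under an exponential (constant-hazard) model:
#' \eqn{S_0(t) = S_0(h)^{t/h}}. For the Framingham 10-year values this gives
#' e.g. \eqn{0.96246^{0.75} = 0.9717} at 7.5 years.
#'
#' @param value Survival probability, strictly in (0, 1).
#' @param horizon Horizon in years the value refers to.
#' @param method One of `"exponential_transform"`, `"kaplan_meier"`,
#'   `"cox_at_means"`.
#' @return An object of class `baseline_survival` with fields `value`,
#'   `horizon`, `method`.
#' @export
baseline_survival <- function(value, horizon, method = c("exponential_transform",
                                                         "kaplan_meier",
                                                         "cox_at_means")) {
  method <- match.arg(method)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) ||
      value <= 0 || value > 1) {
    abort("Baseline survival `value` must be a single number in (0, 1].")
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0) {
    abort("`horizon` must be a single positive number of years.")
  }
  structure(list(value = value, horizon = horizon, method = method),
            class = "baseline_survival")
}

#' @rdname baseline_survival
#' @param s0 A `baseline_survival` object, or a bare survival probability
#'   (then assumed to refer to `from` years).
#' @param t Target horizon in years.
#' @param from Horizon in years that a bare `s0` value refers to
#'   (default 10).
#' @export
horizon_baseline_survival <- function(s0, t, from = 10) {
  if (!inherits(s0, "baseline_survival")) s0 <- baseline_survival(s0, from)
  if (!is.numeric(t) || length(t) != 1 || t <= 0) abort("`t` must be > 0.")
  baseline_survival(s0$value^(t / s0$horizon), t, method = "exponential_transform")
}

#' @export
print.baseline_survival <- function(x, ...) {
  cat(sprintf("<baseline_survival> S0(%g y) = %.4f [%s]\n",
              x$horizon, x$value, x$method))
  invisible(x)
}

#' Sex-specific risk-equation coefficient sets
#'
#' A coefficient set holds everything needed to turn a risk-factor profile
#' into a predicted event probability: per-term log-hazard coefficients
#' \eqn{\beta_j} (reference categories carry an implicit 0), the reference
#' means \eqn{\bar x_j} of the same terms, and a baseline survival
#' \eqn{S_0(t)} at the mean risk profile. The predicted risk at horizon *t*
#' is \eqn{1 - S_0(t)^{\exp(L - \bar L)}} with \eqn{L = \sum_j \beta_j x_j}
#' and \eqn{\bar L = \sum_j \beta_j \bar x_j}.
#'
#' Term names are `age`, `age_sq`, `diabetes`, `smoking_current`, and
#' `tc_*` / `hdl_*` / `bp_*` category indicators using the labels of
#' [frs_categories()] (or collapsed labels, see `collapse`).
#'
#' @param sex `"female"` or `"male"`.
#' @param terms Named numeric vector of coefficients.
#' @param means Named numeric vector of reference means over exactly the
#'   same terms (category prevalences for indicators; the mean of squared
#'   age for `age_sq`).
#' @param baseline A [baseline_survival()].
#' @param provenance Free-text tag (`"wilson1998"`, `"recalibrated"`,
#'   `"refit"`, ...).
#' @param collapse Optional named list of category-merge maps applied after
#'   categorization, e.g. `list(hdl = c("<35" = "<45", "35-44" = "<45"))`.
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(sex, terms, means, baseline,
                            provenance = "custom", collapse = NULL) {
  sex <- match.arg(sex, c("female", "male"))
  if (is.null(names(terms)) || any(names(terms) == "") || anyDuplicated(names(terms))) {
    abort("`terms` must be a uniquely named numeric vector.")
  }
  if (!setequal(names(terms), names(means))) {
    missing_means <- setdiff(names(terms), names(means))
    extra <- setdiff(names(means), names(terms))
    abort(sprintf("`means` must cover exactly the coefficient terms (missing: %s; extra: %s).",
                  paste(missing_means, collapse = ", "), paste(extra, collapse = ", ")))
  }
  means <- means[names(terms)]
  ind <- grep("^(tc_|hdl_|bp_)|^diabetes$|^smoking_current$", names(means))
  if (any(means[ind] < 0 | means[ind] > 1)) {
    abort("Indicator-term means must lie in [0, 1].")
  }
  if (!inherits(baseline, "baseline_survival")) abort("`baseline` must be a baseline_survival().")
  structure(
    list(sex = sex, terms = terms, means = means, baseline = baseline,
         provenance = provenance, collapse = collapse),
    class = "coefficient_set"
  )
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> %s, %d terms, S0(%g y) = %.4f [%s], provenance: %s\n",
              x$sex, length(x$terms), x$baseline$horizon, x$baseline$value,
              x$baseline$method, x$provenance))
  invisible(x)
}

#' @export
tidy.coefficient_set <- function(x, ...) {
  tibble::tibble(term = names(x$terms),
                 estimate = unname(x$terms),
                 mean = unname(x$means))
}

#' Evaluate risk-equation terms on a cohort
#'
#' Builds the numeric design matrix of a coefficient set's terms for every
#' row of a cohort: continuous `age` (and `age_sq` = age squared), 0/1
#' category indicators for total cholesterol, HDL and blood-pressure
#' categories, `diabetes` and `smoking_current`. Categorical columns are
#' derived with [categorize_risk_factors()] when absent and merged through
#' the set's `collapse` maps when present.
#'
#' @param cohort A cohort tibble.
#' @param terms Character vector of term names, or a `coefficient_set`.
#' @param scheme A [frs_categories()] scheme.
#' @param collapse Optional category-merge maps (taken from `terms` when it
#'   is a `coefficient_set`).
#' @return A numeric matrix with one column per term.
#' @export
term_matrix <- function(cohort, terms, scheme = frs_categories(), collapse = NULL) {
  if (inherits(terms, "coefficient_set")) {
    collapse <- collapse %||% terms$collapse
    terms <- names(terms$terms)
  }
  data <- cohort
  if (!all(c("tc_cat", "hdl_cat", "bp_cat", "current_smoker") %in% names(data)) &&
      any(grepl("^(tc_|hdl_|bp_|smoking_current)", terms))) {
    data <- categorize_risk_factors(data, scheme)
  }
  cats <- list(tc = data[["tc_cat"]], hdl = data[["hdl_cat"]], bp = data[["bp_cat"]])
  for (nm in names(collapse %||% list())) {
    map <- collapse[[nm]]
    lev <- as.character(cats[[nm]])
    hit <- lev %in% names(map)
    lev[hit] <- unname(map[lev[hit]])
    cats[[nm]] <- lev
  }
  n <- nrow(data)
  X <- matrix(NA_real_, n, length(terms), dimnames = list(NULL, terms))
  for (term in terms) {
    X[, term] <- switch(
      term,
      age = data$age,
      age_sq = data$age^2,
      diabetes = as.numeric(data$diabetes),
      smoking_current = as.numeric(data$current_smoker %||%
                                     as.integer(data$smoking == "current")),
      {
        pre <- sub("_.*$", "", term)
        lbl <- sub("^(tc|hdl|bp)_", "", term)
        if (!pre %in% names(cats) || is.null(cats[[pre]])) {
          abort(sprintf("Unknown term `%s`.", term))
        }
        as.numeric(as.character(cats[[pre]]) == lbl)
      }
    )
  }
  X
}

#' Linear predictor of a risk equation
#'
#' @param cohort A cohort tibble.
#' @param coefs A [coefficient_set()].
#' @param scheme A [frs_categories()] scheme.
#' @return Numeric vector \eqn{L_i = \sum_j \beta_j x_{ij}}.
#' @export
linear_predictor <- function(cohort, coefs, scheme = frs_categories()) {
  X <- term_matrix(cohort, coefs, scheme = scheme)
  if (anyNA(X)) abort("Risk factors required by the coefficient set are missing; run apply_exclusions() first.")
  drop(X %*% coefs$terms)
}

#' @rdname linear_predictor
#' @export
mean_linear_predictor <- function(coefs) {
  sum(coefs$terms * coefs$means)
}

#' Read and write coefficient-set JSON files
#'
#' The JSON layout mirrors [coefficient_set()]: objects with fields `sex`,
#' `provenance`, `terms`, `means`, `baseline` (`value`, `horizon`,
#' `method`) and optional `collapse`. A file may hold one set or a
#' `{"female": ..., "male": ...}` pair.
#'
#' @param path File path.
#' @return `read_coefficient_set()` returns a `coefficient_set` or a named
#'   list of them.
#' @export
read_coefficient_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_one <- function(o) {
    collapse <- o$collapse
    if (!is.null(collapse)) collapse <- lapply(collapse, unlist)
    coefficient_set(
      sex = o$sex,
      terms = unlist(o$terms),
      means = unlist(o$means),
      baseline = baseline_survival(o$baseline$value, o$baseline$horizon,
                                   o$baseline$method),
      provenance = o$provenance %||% "file",
      collapse = collapse
    )
  }
  if (!is.null(obj$terms)) parse_one(obj)
  else lapply(obj[intersect(c("female", "male"), names(obj))], parse_one)
}

#' @rdname read_coefficient_set
#' @param x A `coefficient_set` or named list of them.
#' @export
write_coefficient_set <- function(x, path) {
  as_list <- function(cs) {
    list(sex = cs$sex, provenance = cs$provenance,
         terms = as.list(cs$terms), means = as.list(cs$means),
         baseline = list(value = cs$baseline$value,
                         horizon = cs$baseline$horizon,
                         method = cs$baseline$method),
         collapse = lapply(cs$collapse %||% list(), as.list))
  }
  out <- if (inherits(x, "coefficient_set")) as_list(x) else lapply(x, as_list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The packaged Framingham (Wilson 1998) coefficient sets
#'
#' Sex-specific coefficients of the categorized Framingham CHD equations and
#' their 10-year baseline survivals (0.96246 women, 0.90015 men), as used
#' throughout this package. The bundled *reference means* are synthetic
#' stand-ins: plausible values for a white middle-aged cohort of the 1970s,
#' clearly tagged as such in the JSON, because the original reference means
#' are not redistributed here. Every function accepts an explicit
#' `coefficient_set`, so analyses that need the authentic means can supply
#' them via [read_coefficient_set()].
#'
#' @param sex `"both"` (default, returns a named list), `"female"` or
#'   `"male"`.
#' @return A `coefficient_set` or a list with elements `female` and `male`.
#' @export
frs_coefficients <- function(sex = c("both", "female", "male")) {
  sex <- match.arg(sex)
  path <- system.file("extdata", "frs_wilson1998_synthetic_means.json",
                      package = "frscal", mustWork = TRUE)
  sets <- read_coefficient_set(path)
  if (sex == "both") sets else sets[[sex]]
}
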