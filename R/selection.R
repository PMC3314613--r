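# Exploratory predictor selection over extended covariates. In these
# models continuous risk factors enter linearly (not categorized); skewed
# laboratory values are log-transformed.

cox_formula_fit <- function(cohort, terms, allow_null = TRUE) {
  if (length(terms) == 0) {
    if (!allow_null) abort("No terms to fit.")
    fit <- survival::coxph(survival::Surv(time, event) ~ 1, data = cohort)
    return(fit)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  warnings_seen <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  diverged <- any(grepl("infinite", warnings_seen)) && any(abs(coef(fit)) > 10)
  if (any(grepl("Ran out of iterations", warnings_seen)) || diverged ||
      anyNA(coef(fit))) {
    abort(sprintf("Cox fit failed for terms: %s.", paste(terms, collapse = " + ")))
  }
  fit
}

cox_loglik <- function(fit) fit$loglik[length(fit$loglik)]

selection_criterion <- function(fit, criterion, d) {
  k <- length(coef(fit))
  pen <- if (criterion == "aic") 2 else log(d)
  -2 * cox_loglik(fit) + pen * k
}

# joint Wald p-value per model term (multi-level factors pooled)
term_wald <- function(fit) {
  if (length(coef(fit)) == 0) return(tibble::tibble(term = character(), df = integer(),
                                                    chisq = double(), p.value = double()))
  assign <- fit$assign
  purrr::map_dfr(names(assign), function(tm) {
    w <- wald_test(fit, assign[[tm]])
    tibble::tibble(term = tm, df = w$df, chisq = w$chisq, p.value = w$p)
  })
}

#' Screen candidate predictors with unadjusted Cox models
#'
#' Fits a single-predictor Cox model per candidate and retains those whose
#' joint Wald p-value is below `alpha` (default 0.20, a deliberately
#' permissive screen). Continuous candidates enter linearly; candidates
#' listed in `log_transform` are log-transformed (skewed laboratory
#' values). Candidates whose model cannot be fitted are logged and
#' skipped.
#'
#' @param cohort A cohort tibble.
#' @param candidates Character vector of model terms: column names or
#'   formula expressions such as `"log(creatinine)"` or
#'   `"I(total_cholesterol/hdl_cholesterol)"`. Default:
#'   [habc_candidates()].
#' @param alpha Retention threshold on the Wald p-value.
#' @param log_transform Columns to wrap in `log()` when they appear as bare
#'   names.
#' @return A tibble with `candidate`, `term`, `df`, `chisq`, `p.value` and
#'   `retained` (NA when the fit failed).
#' @export
univariate_screen <- function(cohort, candidates = habc_candidates(),
                              alpha = 0.20,
                              log_transform = c("triglycerides", "creatinine")) {
  purrr::map_dfr(candidates, function(cand) {
    term <- if (cand %in% log_transform) sprintf("log(%s)", cand) else cand
    fit <- tryCatch(cox_formula_fit(cohort, term, allow_null = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      rlang::inform(sprintf("Candidate `%s` could not be fitted; skipped.", cand))
      return(tibble::tibble(candidate = cand, term = term, df = NA_integer_,
                            chisq = NA_real_, p.value = NA_real_,
                            retained = NA))
    }
    w <- wald_test(fit)
    tibble::tibble(candidate = cand, term = term, df = w$df, chisq = w$chisq,
                   p.value = w$p, retained = w$p < alpha)
  })
}

#' @rdname univariate_screen
#' @export
habc_candidates <- function() {
  c("age", "sex", "smoking", "diabetes", "bmi", "waist_cm", "sbp", "dbp",
    "hdl_cholesterol", "I(total_cholesterol/hdl_cholesterol)", "glucose",
    "log(creatinine)", "aspirin", "physical_activity")
}

new_selection_trace <- function(steps, final_terms, fit, strategy) {
  structure(list(steps = steps, final_terms = final_terms, fit = fit,
                 strategy = strategy),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %s: %d step(s); final model: %s\n",
              x$strategy, nrow(x$steps),
              if (length(x$final_terms)) paste(x$final_terms, collapse = " + ") else "(null)"))
  invisible(x)
}

#' @export
tidy.selection_trace <- function(x, ...) x$steps

#' @export
glance.selection_trace <- function(x, ...) {
  d <- x$fit$nevent
  k <- length(coef(x$fit))
  ll <- cox_loglik(x$fit)
  tibble::tibble(strategy = x$strategy, n_steps = nrow(x$steps), k = k,
                 loglik = ll, aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(d),
                 terms = paste(x$final_terms, collapse = " + "))
}

#' Backward elimination on Wald p-values
#'
#' Starting from the full model, repeatedly drops the term with the largest
#' joint Wald p-value at or above `p_stay` and refits, stopping when every
#' remaining term has p below `p_stay` (default 0.10).
#'
#' @param cohort A cohort tibble.
#' @param terms Character vector of model terms for the full model.
#' @param p_stay Retention threshold.
#' @return A `selection_trace`: `tidy()` gives the step log, `glance()` the
#'   final model summary.
#' @export
backward_select <- function(cohort, terms, p_stay = 0.10) {
  steps <- tibble::tibble(step = integer(), action = character(),
                          term = character(), p.value = double(),
                          loglik = double(), k = integer())
  current <- terms
  fit <- cox_formula_fit(cohort, current, allow_null = TRUE)
  step <- 0L
  while (length(current) > 0) {
    ptab <- term_wald(fit)
    worst <- ptab[which.max(ptab$p.value), ]
    if (worst$p.value < p_stay) break
    step <- step + 1L
    current <- setdiff(current, worst$term)
    fit <- cox_formula_fit(cohort, current, allow_null = TRUE)
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = step, action = "drop", term = worst$term,
      p.value = worst$p.value, loglik = cox_loglik(fit),
      k = length(coef(fit))))
  }
  new_selection_trace(steps, current, fit, sprintf("backward (p < %g)", p_stay))
}

#' Forward stepwise selection minimizing AIC or BIC
#'
#' Starting from the null model, greedily adds the candidate that most
#' decreases the chosen criterion, stopping when no addition decreases it.
#' AIC = -2 logPL + 2k; BIC = -2 logPL + k log(d) with d the number of
#' events (the effective sample size of a partial likelihood).
#'
#' @param cohort A cohort tibble.
#' @param candidates Character vector of candidate model terms.
#' @param criterion `"aic"` or `"bic"`.
#' @return A `selection_trace` whose step log records the criterion before
#'   and after each addition.
#' @export
forward_stepwise <- function(cohort, candidates, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  d <- sum(cohort$event)
  if (d < 1) abort("At least one event is required.")
  current <- character()
  fit <- cox_formula_fit(cohort, current)
  crit <- selection_criterion(fit, criterion, d)
  remaining <- candidates
  steps <- tibble::tibble(step = integer(), action = character(),
                          term = character(), criterion_before = double(),
                          criterion_after = double(), k = integer())
  step <- 0L
  while (length(remaining) > 0) {
    trial <- purrr::map_dbl(remaining, function(cand) {
      f <- tryCatch(cox_formula_fit(cohort, c(current, cand), allow_null = FALSE),
                    error = function(e) NULL)
      if (is.null(f)) Inf else selection_criterion(f, criterion, d)
    })
    best <- which.min(trial)
    if (!is.finite(trial[best]) || trial[best] >= crit) break
    step <- step + 1L
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = step, action = "add", term = remaining[best],
      criterion_before = crit, criterion_after = trial[best],
      k = length(current) + 1L))
    current <- c(current, remaining[best])
    crit <- trial[best]
    remaining <- remaining[-best]
    fit <- cox_formula_fit(cohort, current)
  }
  new_selection_trace(steps, current, fit, toupper(criterion))
}
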