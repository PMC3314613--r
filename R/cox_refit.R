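#' Model term specification for a Cox refit
#'
#' Describes which risk-factor terms enter a refit Cox model and how the
#' original Framingham categories are pooled. Category pooling exists to
#' avoid cells with very few events; `habc_terms()` returns the package's
#' default per-sex specifications for an elderly cohort, in which the pooled
#' and dropped categories are: women — total cholesterol and age-squared
#' dropped, HDL <35 pooled with 35-44, blood-pressure stages I and II-IV
#' pooled; men — TC 200-239 pooled with the 160-199 referent and >=280 with
#' 240-279, HDL <35/35-44/45-49 pooled as the referent, and high-normal
#' pressure pooled with stages I-IV. These defaults are overridable data,
#' not fixed behaviour.
#'
#' @param sex `"female"` or `"male"`.
#' @param continuous Character vector of continuous terms (`"age"`,
#'   `"age_sq"`).
#' @param factors Named list over `tc`, `hdl`, `bp`; each element a list
#'   with `collapse` (named map original level -> merged level, or NULL)
#'   and `reference` (the merged reference level).
#' @param indicators Character vector of 0/1 terms (`"diabetes"`,
#'   `"smoking_current"`).
#' @return An object of class `term_spec`.
#' @export
term_spec <- function(sex, continuous = character(), factors = list(),
                      indicators = character()) {
  sex <- match.arg(sex, c("female", "male"))
  bad <- setdiff(names(factors), c("tc", "hdl", "bp"))
  if (length(bad) > 0) abort(sprintf("Unknown factor(s): %s.", paste(bad, collapse = ", ")))
  structure(list(sex = sex, continuous = continuous, factors = factors,
                 indicators = indicators),
            class = "term_spec")
}

#' @rdname term_spec
#' @export
habc_terms <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female") {
    term_spec(
      "female",
      continuous = "age",
      factors = list(
        hdl = list(collapse = c("<35" = "<45", "35-44" = "<45"),
                   reference = "50-59"),
        bp = list(collapse = c("stage1" = "stage1_4", "stage2_4" = "stage1_4"),
                  reference = "normal")
      ),
      indicators = c("diabetes", "smoking_current")
    )
  } else {
    term_spec(
      "male",
      continuous = "age",
      factors = list(
        tc = list(collapse = c("160-199" = "160-239", "200-239" = "160-239",
                               "240-279" = ">=240", ">=280" = ">=240"),
                  reference = "160-239"),
        hdl = list(collapse = c("<35" = "<50", "35-44" = "<50", "45-49" = "<50"),
                   reference = "<50"),
        bp = list(collapse = c("high_normal" = "high_normal_4",
                               "stage1" = "high_normal_4",
                               "stage2_4" = "high_normal_4"),
                  reference = "normal")
      ),
      indicators = c("diabetes", "smoking_current")
    )
  }
}

# expand a term_spec into coefficient-style term names + collapse maps
spec_terms <- function(spec, scheme = frs_categories()) {
  full_levels <- list(tc = scheme$tc_levels, hdl = scheme$hdl_levels,
                      bp = scheme$bp_levels)
  terms <- spec$continuous
  collapse <- list()
  for (nm in names(spec$factors)) {
    f <- spec$factors[[nm]]
    lev <- full_levels[[nm]]
    if (!is.null(f$collapse)) {
      collapse[[nm]] <- f$collapse
      hit <- lev %in% names(f$collapse)
      lev[hit] <- unname(f$collapse[lev[hit]])
      lev <- unique(lev)
    }
    if (!f$reference %in% lev) {
      abort(sprintf("Reference level `%s` is not a (merged) %s level.", f$reference, nm))
    }
    terms <- c(terms, paste0(nm, "_", setdiff(lev, f$reference)))
  }
  terms <- c(terms, spec$indicators)
  list(terms = terms, collapse = if (length(collapse)) collapse else NULL)
}

#' Fit a Cox proportional-hazards model to a cohort
#'
#' Fits the refit ("cohort-specific") risk function: a Cox model on the
#' cohort's categorized risk factors with the pooling given by a
#' [term_spec()]. The partial likelihood is maximized by Newton-Raphson
#' (Efron tie handling by default, convergence tolerance 1e-9, at most 50
#' iterations) via the survival package. Category indicators enter as
#' explicit 0/1 columns so coefficient names match [coefficient_set()]
#' terms.
#'
#' @param cohort A cohort tibble with at least one event.
#' @param terms A [term_spec()] (default [habc_terms()] for the cohort's
#'   single sex) or the result of an earlier `fit_cox()`'s spec.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param scheme A [frs_categories()] scheme.
#' @return An object of class `cox_refit`: the fitted model plus metadata
#'   (`n`, `n_events`, log partial likelihoods, the term spec). Supports
#'   [tidy()], [glance()], [hazard_ratios()], [ph_test()],
#'   [baseline_survival_at_means()], [refit_risk()].
#' @export
fit_cox <- function(cohort, terms = NULL, ties = c("efron", "breslow"),
                    scheme = frs_categories()) {
  ties <- match.arg(ties)
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  if (sum(cohort$event) < 1) abort("At least one event is required to fit a Cox model.")
  if (is.null(terms)) {
    sexes <- unique(as.character(cohort$sex))
    if (length(sexes) != 1) {
      abort("Supply `terms` explicitly, or restrict the cohort to one sex to use the default habc_terms().")
    }
    terms <- habc_terms(sexes)
  }
  st <- spec_terms(terms, scheme)
  if (length(st$terms) == 0) {
    fit <- survival::coxph(survival::Surv(time, event) ~ 1,
                           data = cohort[c("time", "event")])
    return(structure(list(fit = fit, spec = terms, scheme = scheme,
                          term_names = character(), n = nrow(cohort),
                          n_events = sum(cohort$event),
                          loglik = c(fit$loglik[1], fit$loglik[1]),
                          data = cohort[c("time", "event")]),
                     class = "cox_refit"))
  }
  X <- term_matrix(cohort, st$terms, scheme = scheme, collapse = st$collapse)
  if (anyNA(X)) abort("Missing risk factors; run apply_exclusions() first.")
  const <- colnames(X)[apply(X, 2, function(v) length(unique(v)) == 1)]
  if (length(const) > 0) {
    abort(sprintf("Zero-variance term(s): %s.", paste(const, collapse = ", ")))
  }
  ind <- grep("^(tc_|hdl_|bp_)|^diabetes$|^smoking_current$", colnames(X), value = TRUE)
  no_event <- ind[vapply(ind, function(tm) sum(cohort$event[X[, tm] == 1]) == 0, TRUE)]
  if (length(no_event) > 0) {
    warn(sprintf("Term level(s) with no events (estimates will be unstable): %s.",
                 paste(no_event, collapse = ", ")))
  }
  df <- cbind(cohort[c("time", "event")], as.data.frame(X))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  warnings_seen <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50),
                    x = TRUE),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (any(grepl("Ran out of iterations", warnings_seen))) {
    abort(paste0("Cox fit did not converge: ",
                 paste(unique(warnings_seen), collapse = "; ")))
  }
  # monotone partial likelihood (complete separation): the Newton path
  # diverges; coxph flags it and the estimate runs away on the log scale
  if (any(grepl("infinite", warnings_seen)) && any(abs(coef(fit)) > 10)) {
    abort("Monotone partial likelihood (complete separation): a coefficient diverges.")
  }
  if (anyNA(coef(fit))) {
    abort(sprintf("Singular design: coefficient(s) not estimable: %s.",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  names(fit$coefficients) <- colnames(X)
  structure(
    list(fit = fit, spec = terms, scheme = scheme, term_names = colnames(X),
         n = nrow(cohort), n_events = sum(cohort$event),
         loglik = fit$loglik, data = df),
    class = "cox_refit"
  )
}

#' @export
print.cox_refit <- function(x, ...) {
  cat(sprintf("<cox_refit> %d terms, n = %d, events = %d, logPL = %.2f\n",
              length(x$term_names), x$n, x$n_events, x$loglik[length(x$loglik)]))
  if (length(x$term_names) > 0) print(hazard_ratios(x))
  invisible(x)
}

#' @export
tidy.cox_refit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  if (length(x$term_names) == 0) {
    return(tibble::tibble(term = character(), estimate = double(),
                          std.error = double(), statistic = double(),
                          p.value = double(), conf.low = double(),
                          conf.high = double()))
  }
  b <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = x$term_names,
    estimate = unname(b),
    std.error = unname(se),
    statistic = unname(b / se),
    p.value = 2 * pnorm(-abs(unname(b / se))),
    conf.low = unname(b - z * se),
    conf.high = unname(b + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @export
glance.cox_refit <- function(x, ...) {
  k <- length(x$term_names)
  ll <- x$loglik[length(x$loglik)]
  tibble::tibble(
    n = x$n, n_events = x$n_events, k = k,
    loglik_null = x$loglik[1], loglik = ll,
    aic = -2 * ll + 2 * k,
    bic = -2 * ll + k * log(x$n_events)
  )
}

#' Hazard ratios with 95% confidence intervals
#'
#' @param fit A [fit_cox()] result.
#' @return A tibble with `term`, `estimate` (log hazard ratio),
#'   `std.error`, `hr` = exp(estimate) and its Wald 95% CI, `p.value`.
#' @export
hazard_ratios <- function(fit) {
  td <- tidy(fit)
  tibble::tibble(
    term = td$term, estimate = td$estimate, std.error = td$std.error,
    hr = exp(td$estimate),
    hr.low = exp(td$estimate - 1.96 * td$std.error),
    hr.high = exp(td$estimate + 1.96 * td$std.error),
    p.value = td$p.value
  )
}

#' Baseline survival of a Cox fit at the covariate means
#'
#' The Breslow-type baseline survival of a fitted Cox model evaluated at
#' the mean covariate vector of the fitting data:
#' \eqn{S(t \mid \bar x) = \exp(-\hat\Lambda_0(t) e^{\beta'\bar x}}), using
#' the survival package's centered parameterization (the curve is computed
#' directly at the stored covariate means).
#'
#' @param fit A [fit_cox()] result.
#' @param t Time in years. Beyond the last observed time the last value is
#'   returned with a warning.
#' @return A [baseline_survival()] with method `"cox_at_means"`.
#' @export
baseline_survival_at_means <- function(fit, t) {
  if (!inherits(fit, "cox_refit")) abort("`fit` must come from fit_cox().")
  if (!is.numeric(t) || length(t) != 1 || t <= 0) abort("`t` must be > 0.")
  sf <- survival::survfit(fit$fit, se.fit = FALSE, stype = 2, ctype = 1)
  if (t > max(sf$time)) {
    warn(sprintf("t = %g is beyond the last observed time (%g); returning the last value.",
                 t, max(sf$time)))
  }
  keep <- sf$time <= t
  value <- if (any(keep)) sf$surv[max(which(keep))] else 1
  baseline_survival(value, t, method = "cox_at_means")
}

#' Per-person predicted risk from a refit Cox model
#'
#' The same risk transform as [frs_score()] —
#' \eqn{1 - S_0(t)^{\exp(L - \bar L)}} — but with the refit coefficients,
#' the fitting cohort's covariate means, and the Cox baseline survival at
#' those means.
#'
#' @param fit A [fit_cox()] result.
#' @param cohort Cohort to score (default: the fitting data).
#' @param horizon Horizon in years (default: cohort attribute or 7.5).
#' @return The cohort with `.lp` (mean-centered linear predictor), `.risk`
#'   and `.model = "refit"` appended.
#' @export
refit_risk <- function(fit, cohort = NULL, horizon = NULL) {
  if (!inherits(fit, "cox_refit")) abort("`fit` must come from fit_cox().")
  if (is.null(cohort)) {
    # score the fitting data: linear predictors are already mean-centered
    horizon <- horizon %||% 7.5
    s0 <- baseline_survival_at_means(fit, horizon)
    out <- tibble::as_tibble(fit$data)
    out$.lp <- if (length(fit$term_names) == 0) rep(0, nrow(out)) else
      unname(fit$fit$linear.predictors)
    out$.risk <- predicted_risk(out$.lp, 0, s0)
    out$.model <- "refit"
    attr(out, "horizon") <- horizon
    return(out)
  }
  horizon <- horizon %||% cohort_horizon(cohort)
  s0 <- baseline_survival_at_means(fit, horizon)
  if (length(fit$term_names) == 0) {
    lp <- rep(0, nrow(cohort))
  } else {
    st <- spec_terms(fit$spec, fit$scheme)
    X <- term_matrix(cohort, st$terms, scheme = fit$scheme, collapse = st$collapse)
    lp <- drop(X %*% coef(fit$fit)) - sum(coef(fit$fit) * fit$fit$means)
  }
  out <- cohort
  out$.lp <- lp
  out$.risk <- predicted_risk(lp, 0, s0)
  out$.model <- "refit"
  attr(out, "horizon") <- horizon
  out
}

#' Convert a Cox refit into a portable coefficient set
#'
#' @param fit A [fit_cox()] result.
#' @param horizon Horizon in years for the stored baseline survival.
#' @return A [coefficient_set()] with provenance `"refit"`, usable with
#'   [frs_score()] and [write_coefficient_set()].
#' @export
as_coefficient_set <- function(fit, horizon = 7.5) {
  if (!inherits(fit, "cox_refit")) abort("`fit` must come from fit_cox().")
  st <- spec_terms(fit$spec, fit$scheme)
  coefficient_set(
    sex = fit$spec$sex,
    terms = setNames(as.numeric(coef(fit$fit)), fit$term_names),
    means = setNames(as.numeric(fit$fit$means), fit$term_names),
    baseline = baseline_survival_at_means(fit, horizon),
    provenance = "refit",
    collapse = st$collapse
  )
}

#' Proportional-hazards diagnostic (Schoenfeld residual test)
#'
#' The score test of Therneau and Grambsch: scaled Schoenfeld residuals are
#' regressed on a transform of event time (Kaplan-Meier transform by
#' default); a non-zero slope indicates a time-varying effect, i.e. a
#' proportional-hazards violation.
#'
#' @param fit A [fit_cox()] result with at least two events.
#' @param transform `"km"` (default), `"identity"` or `"rank"`.
#' @return An object of class `ph_test_result`; `tidy()` returns per-term
#'   rows plus a `GLOBAL` row with `chisq`, `df`, `p.value`.
#' @export
ph_test <- function(fit, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  if (!inherits(fit, "cox_refit")) abort("`fit` must come from fit_cox().")
  if (fit$n_events < 2) abort("At least two events are required for the proportional-hazards test.")
  if (length(fit$term_names) == 0) abort("The null model has no terms to test.")
  zp <- survival::cox.zph(fit$fit, transform = transform, global = TRUE)
  tab <- tibble::tibble(
    term = gsub("`", "", rownames(zp$table)),
    chisq = unname(zp$table[, "chisq"]),
    df = unname(zp$table[, "df"]),
    p.value = unname(zp$table[, "p"])
  )
  tab$term[tab$term == "GLOBAL"] <- "GLOBAL"
  structure(list(table = tab, transform = transform), class = "ph_test_result")
}

#' @export
print.ph_test_result <- function(x, ...) {
  g <- x$table[x$table$term == "GLOBAL", ]
  cat(sprintf("<ph_test_result> global chisq = %.3f on %d df, p = %.3f (transform: %s)\n",
              g$chisq, g$df, g$p.value, x$transform))
  invisible(x)
}

#' @export
tidy.ph_test_result <- function(x, ...) x$table

#' @export
glance.ph_test_result <- function(x, ...) {
  g <- x$table[x$table$term == "GLOBAL", ]
  tibble::tibble(chisq = g$chisq, df = g$df, p.value = g$p.value,
                 transform = x$transform)
}
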