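#' Cohort means of risk-equation terms
#'
#' The per-term means \eqn{\bar x_j} of a coefficient set's terms on a
#' cohort: arithmetic means for continuous terms (the mean of squared ages
#' for `age_sq`), category prevalences for indicator terms. These are the
#' means substituted into a risk equation when recalibrating it to the
#' cohort.
#'
#' @param cohort A non-empty cohort tibble.
#' @param coefs A [coefficient_set()].
#' @param scheme A [frs_categories()] scheme.
#' @return Named numeric vector over the coefficient set's terms.
#' @export
cohort_means <- function(cohort, coefs, scheme = frs_categories()) {
  if (nrow(cohort) == 0) abort("Cannot take risk-factor means of an empty cohort.")
  X <- term_matrix(cohort, coefs, scheme = scheme)
  if (anyNA(X)) abort("Missing risk factors; run apply_exclusions() first.")
  colMeans(X)
}

#' Kaplan-Meier survival of a cohort at a time point
#'
#' Product-limit estimate \eqn{\prod_{t_i \le t} (1 - d_i / n_i)} under
#' right censoring, evaluated with the right-continuous step convention
#' (the value at the largest event time \eqn{\le t}). Ties between events
#' and censorings at the same time are resolved with events first.
#'
#' @param cohort A non-empty cohort tibble with `time` and `event` columns.
#' @param t Evaluation time in years (>= 0).
#' @return An object of class `km_estimate` with fields `value` (survival
#'   at `t`), `time` (`t`), `n`, `n_events`, and the step function as
#'   `step_times` / `step_surv`.
#' @export
km_survival <- function(cohort, t) {
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  if (!is.numeric(t) || length(t) != 1 || t < 0) abort("`t` must be a single time >= 0.")
  sf <- survival::survfit(survival::Surv(cohort$time, cohort$event) ~ 1,
                          se.fit = FALSE)
  keep <- sf$time <= t
  value <- if (any(keep)) sf$surv[max(which(keep))] else 1
  structure(
    list(value = value, time = t, n = nrow(cohort),
         n_events = sum(cohort$event),
         step_times = sf$time, step_surv = sf$surv),
    class = "km_estimate"
  )
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> S(%g y) = %.4f  (n = %d, events = %d)\n",
              x$time, x$value, x$n, x$n_events))
  invisible(x)
}

#' Recalibrate a risk equation to a cohort
#'
#' Transports an external risk equation to a new population: the original
#' coefficients are retained bitwise, the reference means are replaced by
#' the cohort's own term means, and the baseline survival is replaced by
#' the cohort's Kaplan-Meier survival at the horizon. Because the linear
#' predictor is unchanged, recalibration is a strictly monotone transform
#' of the original score: it changes absolute risks (calibration) but never
#' their ranking (discrimination).
#'
#' Recalibration is sex-specific: the cohort must contain only participants
#' of the set's sex. `recalibrate_frs()` is a convenience wrapper that
#' stratifies a mixed cohort and returns a per-sex list ready for
#' [frs_score()].
#'
#' @param coefs A [coefficient_set()].
#' @param cohort A cohort tibble restricted to `coefs$sex`.
#' @param horizon Horizon in years (default: cohort attribute or 7.5).
#' @param scheme A [frs_categories()] scheme.
#' @return A new `coefficient_set` with provenance `"recalibrated"` and a
#'   `kaplan_meier` baseline.
#' @export
recalibrate <- function(coefs, cohort, horizon = NULL, scheme = frs_categories()) {
  horizon <- horizon %||% cohort_horizon(cohort)
  if (!inherits(coefs, "coefficient_set")) abort("`coefs` must be a coefficient_set().")
  if (!all(as.character(cohort$sex) == coefs$sex)) {
    abort(sprintf("Recalibration is sex-specific: cohort must contain only %s participants.",
                  coefs$sex))
  }
  km <- km_survival(cohort, horizon)
  if (km$value <= 0 || km$value >= 1) {
    abort("Kaplan-Meier survival at the horizon must be strictly in (0, 1) to serve as a baseline.")
  }
  coefficient_set(
    sex = coefs$sex,
    terms = coefs$terms,
    means = cohort_means(cohort, coefs, scheme = scheme),
    baseline = baseline_survival(km$value, horizon, method = "kaplan_meier"),
    provenance = "recalibrated",
    collapse = coefs$collapse
  )
}

#' @rdname recalibrate
#' @export
recalibrate_frs <- function(cohort, coefs = frs_coefficients(), horizon = NULL,
                            scheme = frs_categories()) {
  horizon <- horizon %||% cohort_horizon(cohort)
  sexes <- intersect(c("female", "male"), unique(as.character(cohort$sex)))
  out <- lapply(sexes, function(s) {
    recalibrate(coefs[[s]], cohort[as.character(cohort$sex) == s, , drop = FALSE],
                horizon = horizon, scheme = scheme)
  })
  setNames(out, sexes)
}
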