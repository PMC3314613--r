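#' Predicted event probability from a linear predictor
#'
#' The survival-model risk transform
#' \eqn{\hat p = 1 - S_0(t)^{\exp(L - \bar L)}}: the baseline survival at
#' the horizon, raised to the person's hazard ratio relative to the mean
#' risk profile. Strictly increasing in `lp`, bounded in (0, 1).
#'
#' @param lp Numeric vector of linear predictors \eqn{L}.
#' @param lp_bar Linear predictor at the reference means \eqn{\bar L}.
#' @param s0 A [baseline_survival()] at the target horizon.
#' @return Numeric vector of event probabilities.
#' @export
predicted_risk <- function(lp, lp_bar, s0) {
  if (!inherits(s0, "baseline_survival")) abort("`s0` must be a baseline_survival().")
  1 - s0$value^exp(lp - lp_bar)
}

resolve_baseline <- function(coefs, horizon) {
  b <- coefs$baseline
  if (isTRUE(all.equal(b$horizon, horizon))) {
    b
  } else {
    # rescale across horizons under the exponential (constant-hazard) model
    horizon_baseline_survival(b, horizon)
  }
}

#' Score a cohort with a sex-specific risk equation
#'
#' Computes each participant's predicted CHD risk by the target horizon:
#' risk factors are categorized, the sex-appropriate linear predictor
#' \eqn{L} is formed, the baseline survival is rescaled to the horizon under
#' the exponential model when needed, and the risk
#' \eqn{1 - S_0(t)^{\exp(L - \bar L)}} is returned per person.
#'
#' @param cohort A cohort tibble (after [apply_exclusions()]).
#' @param coefs A [coefficient_set()], or a named list with elements
#'   `female` and/or `male` (default: the packaged Framingham sets,
#'   [frs_coefficients()]).
#' @param horizon Prediction horizon in years (default: the cohort's
#'   `horizon` attribute, falling back to 7.5).
#' @param scheme A [frs_categories()] scheme.
#' @return The cohort with columns `.lp` (linear predictor), `.risk`
#'   (predicted probability) and `.model` (the provenance tag of the set
#'   used) appended.
#' @export
frs_score <- function(cohort, coefs = frs_coefficients(), horizon = NULL,
                      scheme = frs_categories()) {
  horizon <- horizon %||% cohort_horizon(cohort)
  if (horizon <= 0) abort("`horizon` must be > 0.")
  if (inherits(coefs, "coefficient_set")) {
    sexes <- unique(as.character(cohort$sex))
    coefs <- setNames(rep(list(coefs), length(sexes)), sexes)
  }
  present <- unique(as.character(cohort$sex))
  missing_sets <- setdiff(present, names(coefs))
  if (length(missing_sets) > 0) {
    abort(sprintf("No coefficient set supplied for sex: %s.",
                  paste(missing_sets, collapse = ", ")))
  }
  out <- cohort
  out$.lp <- NA_real_
  out$.risk <- NA_real_
  out$.model <- NA_character_
  for (s in present) {
    cs <- coefs[[s]]
    rows <- which(as.character(cohort$sex) == s)
    lp <- linear_predictor(cohort[rows, , drop = FALSE], cs, scheme = scheme)
    s0 <- resolve_baseline(cs, horizon)
    out$.lp[rows] <- lp
    out$.risk[rows] <- predicted_risk(lp, mean_linear_predictor(cs), s0)
    out$.model[rows] <- cs$provenance
  }
  if (any(cohort$age > 74, na.rm = TRUE) &&
      any(vapply(coefs[present], function(cs) identical(cs$provenance, "wilson1998"), TRUE))) {
    rlang::inform(
      sprintf("%d participant(s) older than 74 y: the Framingham equation is extrapolated beyond its development age range (ages entered uncapped).",
              sum(cohort$age > 74, na.rm = TRUE)),
      class = "frscal_age_extrapolation")
  }
  attr(out, "horizon") <- horizon
  out
}

#' Clinical 10-year CHD risk classes
#'
#' Bins 10-year predicted risks into the conventional treatment-guidance
#' classes: <5, 5-9.99, 10-19.99 and >=20 percent per 10 years.
#'
#' @param risk10 Numeric vector of 10-year risks as probabilities in
#'   \[0, 1\].
#' @return An ordered factor with levels `"<5%"`, `"5-9.99%"`,
#'   `"10-19.99%"`, `">=20%"`.
#' @export
frs_risk_class <- function(risk10) {
  check_prob(risk10[!is.na(risk10)], "risk10")
  cut(risk10, breaks = c(-Inf, 0.05, 0.10, 0.20, Inf), right = FALSE,
      labels = c("<5%", "5-9.99%", "10-19.99%", ">=20%"), ordered_result = TRUE)
}
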