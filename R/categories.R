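#' Risk-factor category scheme
#'
#' The categorization used by the sex-specific Framingham CHD equations:
#' NCEP total-cholesterol and HDL-cholesterol bins and JNC blood-pressure
#' stages. Bins are left-closed, right-open (a total cholesterol of exactly
#' 160 mg/dL falls in "160-199"). The blood-pressure category for a person
#' is the more severe of the category implied by the systolic and by the
#' diastolic reading.
#'
#' @param tc_breaks,hdl_breaks Interior bin edges in mg/dL.
#' @param sbp_breaks,dbp_breaks Interior stage edges in mmHg (optimal /
#'   normal / high-normal / stage I / stage II-IV).
#' @return An object of class `category_scheme`.
#' @export
frs_categories <- function(tc_breaks = c(160, 200, 240, 280),
                           hdl_breaks = c(35, 45, 50, 60),
                           sbp_breaks = c(120, 130, 140, 160),
                           dbp_breaks = c(80, 85, 90, 100)) {
  for (b in list(tc_breaks, hdl_breaks, sbp_breaks, dbp_breaks)) {
    if (length(b) != 4 || is.unsorted(b, strictly = TRUE)) {
      abort("Category breaks must be 4 strictly increasing values.")
    }
  }
  structure(
    list(
      tc_breaks = tc_breaks, hdl_breaks = hdl_breaks,
      sbp_breaks = sbp_breaks, dbp_breaks = dbp_breaks,
      tc_levels = c("<160", "160-199", "200-239", "240-279", ">=280"),
      hdl_levels = c("<35", "35-44", "45-49", "50-59", ">=60"),
      bp_levels = c("optimal", "normal", "high_normal", "stage1", "stage2_4")
    ),
    class = "category_scheme"
  )
}

bin_left_closed <- function(x, breaks, labels) {
  idx <- findInterval(x, breaks) + 1L
  factor(labels[idx], levels = labels)
}

#' Categorize risk factors for Framingham scoring
#'
#' Adds the categorical risk-factor columns used by the Framingham equations
#' to a cohort: `tc_cat`, `hdl_cat`, `bp_cat` and the `current_smoker`
#' indicator (former smokers count as non-smokers in the Wilson equation).
#'
#' @param cohort A cohort tibble (or any data frame with the required
#'   risk-factor columns).
#' @param scheme A [frs_categories()] scheme.
#' @return The input with columns `tc_cat`, `hdl_cat`, `bp_cat`
#'   (ordered factors from least to most severe) and `current_smoker` added.
#' @export
categorize_risk_factors <- function(cohort, scheme = frs_categories()) {
  if (!inherits(scheme, "category_scheme")) abort("`scheme` must come from frs_categories().")
  for (col in c("total_cholesterol", "hdl_cholesterol", "sbp", "dbp")) {
    if (!col %in% names(cohort)) abort(sprintf("Column `%s` is required.", col))
    bad <- !is.na(cohort[[col]]) & cohort[[col]] <= 0
    if (any(bad)) abort(sprintf("`%s` must be strictly positive.", col))
  }
  sbp_idx <- findInterval(cohort$sbp, scheme$sbp_breaks) + 1L
  dbp_idx <- findInterval(cohort$dbp, scheme$dbp_breaks) + 1L
  bp_idx <- pmax(sbp_idx, dbp_idx)
  out <- cohort
  out$tc_cat <- bin_left_closed(cohort$total_cholesterol, scheme$tc_breaks, scheme$tc_levels)
  out$hdl_cat <- bin_left_closed(cohort$hdl_cholesterol, scheme$hdl_breaks, scheme$hdl_levels)
  out$bp_cat <- factor(scheme$bp_levels[bp_idx], levels = scheme$bp_levels)
  out$current_smoker <- as.integer(!is.na(cohort$smoking) & cohort$smoking == "current")
  out$current_smoker[is.na(cohort$smoking)] <- NA_integer_
  attr(out, "horizon") <- attr(cohort, "horizon")
  out
}
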