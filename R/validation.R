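# Discrimination and calibration of a per-person risk vector against
# censored time-to-event outcomes.

concordance_index <- function(time, event, score) {
  stopifnot(length(time) == length(event), length(time) == length(score))
  conc <- disc <- tied <- 0
  for (i in which(event == 1)) {
    later <- time > time[i] | (time == time[i] & event == 0)
    later[i] <- FALSE
    if (!any(later)) next
    s <- score[later]
    conc <- conc + sum(score[i] > s)
    disc <- disc + sum(score[i] < s)
    tied <- tied + sum(score[i] == s)
  }
  n_pairs <- conc + disc + tied
  list(c = if (n_pairs > 0) (conc + 0.5 * tied) / n_pairs else NA_real_,
       n_pairs = n_pairs, concordant = conc, discordant = disc, tied = tied)
}

#' Harrell's concordance index for censored data
#'
#' The fraction of usable subject pairs ordered concordantly by the score.
#' A pair is usable when the shorter observed time is an event (two events
#' tied in time are not usable; an event tied with a censoring counts, with
#' the event as the earlier). A pair is concordant when the subject with
#' the earlier event carries the higher score; score ties count 1/2.
#'
#' @param data A data frame with follow-up columns.
#' @param score Column of risk scores (default `.risk`, as produced by
#'   [frs_score()] / [refit_risk()]); any strictly increasing transform of
#'   a score gives the identical C.
#' @param time,event Follow-up columns (defaults `time`, `event`).
#' @return A one-row tibble: `c_index`, `n`, `n_pairs`, `concordant`,
#'   `discordant`, `tied`.
#' @export
harrell_c <- function(data, score = .risk, time = time, event = event) {
  t <- rlang::eval_tidy(enquo(time), data)
  e <- rlang::eval_tidy(enquo(event), data)
  s <- rlang::eval_tidy(enquo(score), data)
  res <- concordance_index(t, e, s)
  if (res$n_pairs == 0) abort("No usable pairs: cannot compute a concordance index.")
  tibble::tibble(c_index = res$c, n = length(t), n_pairs = res$n_pairs,
                 concordant = res$concordant, discordant = res$discordant,
                 tied = res$tied)
}

#' Optimism-corrected C-index by bootstrap resampling
#'
#' Harrell's internal-validation procedure for a model evaluated on its own
#' fitting data: for each bootstrap resample, the model is refit and its
#' C-index on the resample is compared with the same model's C-index on the
#' original cohort; the mean difference (the optimism) is subtracted from
#' the apparent C.
#'
#' @param cohort The fitting cohort (single sex unless `terms` is given).
#' @param terms A [term_spec()] passed to [fit_cox()].
#' @param B Number of bootstrap replications (the reference analysis uses
#'   1000).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param horizon Horizon in years (ranking, and hence C, does not depend
#'   on it).
#' @return A one-row tibble: `apparent`, `optimism`, `corrected`, `B`,
#'   `failed_fits`, `seed`. Bootstrap fits that fail are logged and the
#'   replicate redrawn (at most `2 * B` attempts).
#' @export
optimism_corrected_c <- function(cohort, terms = NULL, B = 1000, seed = 1,
                                 horizon = NULL) {
  if (B < 1) abort("`B` must be >= 1.")
  fit0 <- fit_cox(cohort, terms = terms)
  terms <- fit0$spec
  lp0 <- refit_risk(fit0, cohort, horizon = horizon %||% cohort_horizon(cohort))$.lp
  apparent <- concordance_index(cohort$time, cohort$event, lp0)$c
  n <- nrow(cohort)
  set.seed(seed)
  optimism <- numeric(B)
  b <- 0L
  attempts <- 0L
  failed <- 0L
  while (b < B && attempts < 2L * B) {
    attempts <- attempts + 1L
    idx <- sample.int(n, n, replace = TRUE)
    boot <- cohort[idx, , drop = FALSE]
    boot$id <- as.character(seq_len(n))  # resampled rows need unique ids
    fit_b <- tryCatch(suppressWarnings(fit_cox(boot, terms = terms)),
                      error = function(e) NULL)
    if (is.null(fit_b)) {
      failed <- failed + 1L
      next
    }
    lp_boot <- refit_risk(fit_b, boot)$.lp
    lp_orig <- refit_risk(fit_b, cohort)$.lp
    c_boot <- concordance_index(boot$time, boot$event, lp_boot)$c
    c_orig <- concordance_index(cohort$time, cohort$event, lp_orig)$c
    b <- b + 1L
    optimism[b] <- c_boot - c_orig
  }
  if (b < B) {
    abort(sprintf("Only %d of %d bootstrap fits succeeded within %d attempts.",
                  b, B, attempts))
  }
  tibble::tibble(apparent = apparent, optimism = mean(optimism),
                 corrected = apparent - mean(optimism),
                 B = B, failed_fits = failed, seed = seed)
}

# shared decile grouping: returns per-group index list after merging
# groups whose expected count is zero into a neighbor
risk_groups <- function(p, id, groups) {
  g <- stable_groups(p, id, groups)
  idx <- split(seq_along(p), g)
  repeat {
    expected <- vapply(idx, function(i) sum(p[i]), 0)
    bad <- which(expected == 0)
    if (length(bad) == 0 || length(idx) == 1) break
    merge_into <- if (bad[1] < length(idx)) bad[1] + 1L else bad[1] - 1L
    idx[[merge_into]] <- sort(c(idx[[merge_into]], idx[[bad[1]]]))
    idx <- idx[-bad[1]]
    rlang::inform("Merged a risk group with zero expected events into its neighbor.")
  }
  idx
}

#' Decile-based calibration chi-square for censored data
#'
#' An adaptation of the Hosmer-Lemeshow goodness-of-fit test to survival
#' models: subjects are split into groups (deciles by default) of predicted
#' risk; within each group the expected number of events by the horizon is
#' \eqn{E_g = \sum_i \hat p_i} and the observed number is
#' \eqn{O_g = n_g (1 - \hat S_g(t))} with \eqn{\hat S_g} the within-group
#' Kaplan-Meier estimate (so censoring is respected). The statistic
#' \eqn{\sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g))} is referred to a
#' chi-square with `groups - 1` degrees of freedom; larger p-values
#' indicate better calibration.
#'
#' @inheritParams harrell_c
#' @param horizon Horizon in years the risks refer to.
#' @param groups Number of risk groups (default 10). Groups whose expected
#'   count is zero are merged into a neighbor with a message, reducing the
#'   degrees of freedom.
#' @param id Optional column used to break score ties stably (default the
#'   `id` column when present, else row order).
#' @return An object of class `hl_cox_test` with the group table and the
#'   statistic; `glance()` gives `statistic`, `df`, `p.value`, `tidy()`
#'   the per-group table.
#' @export
hl_cox <- function(data, score = .risk, horizon = NULL, groups = 10,
                   time = time, event = event, id = NULL) {
  if (groups < 2) abort("`groups` must be >= 2.")
  horizon <- horizon %||% cohort_horizon(data)
  t <- rlang::eval_tidy(enquo(time), data)
  e <- rlang::eval_tidy(enquo(event), data)
  p <- rlang::eval_tidy(enquo(score), data)
  check_prob(p, "score")
  ids <- id %||% data[["id"]] %||% as.character(seq_along(p))
  idx <- risk_groups(p, ids, groups)
  tab <- purrr::map_dfr(seq_along(idx), function(g) {
    i <- idx[[g]]
    km <- km_value_at(t[i], e[i], horizon)
    tibble::tibble(group = g, n = length(i),
                   mean_predicted = mean(p[i]),
                   expected = sum(p[i]),
                   km_survival = km,
                   observed = length(i) * (1 - km))
  })
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- nrow(tab) - 1L
  structure(
    list(table = tab, statistic = stat, df = df,
         p.value = pchisq(stat, df, lower.tail = FALSE),
         horizon = horizon, groups_requested = groups),
    class = "hl_cox_test"
  )
}

#' @export
print.hl_cox_test <- function(x, ...) {
  cat(sprintf("<hl_cox_test> chi-square = %.2f on %d df, p = %.3g (horizon %g y, %d groups)\n",
              x$statistic, x$df, x$p.value, x$horizon, nrow(x$table)))
  invisible(x)
}

#' @export
tidy.hl_cox_test <- function(x, ...) x$table

#' @export
glance.hl_cox_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 horizon = x$horizon, groups = nrow(x$table))
}

#' Predicted-to-observed risk ratios across risk groups
#'
#' For each group (decile by default) of predicted risk: the mean predicted
#' risk, the observed risk \eqn{1 - \hat S_g(t)} from the within-group
#' Kaplan-Meier estimate, and their ratio (1 = perfect calibration,
#' below 1 = underestimation). A final `overall` row pools all subjects.
#'
#' @inheritParams hl_cox
#' @return A tibble of class `decile_ratio` with columns `group`, `n`,
#'   `mean_predicted`, `observed`, `ratio` (`NA` when the observed risk in
#'   a group is zero).
#' @export
decile_ratio <- function(data, score = .risk, horizon = NULL, groups = 10,
                         time = time, event = event, id = NULL) {
  if (groups < 1) abort("`groups` must be >= 1.")
  horizon <- horizon %||% cohort_horizon(data)
  t <- rlang::eval_tidy(enquo(time), data)
  e <- rlang::eval_tidy(enquo(event), data)
  p <- rlang::eval_tidy(enquo(score), data)
  check_prob(p, "score")
  ids <- id %||% data[["id"]] %||% as.character(seq_along(p))
  idx <- if (groups == 1) list() else risk_groups(p, ids, groups)
  row_for <- function(label, i) {
    obs <- 1 - km_value_at(t[i], e[i], horizon)
    tibble::tibble(group = label, n = length(i), mean_predicted = mean(p[i]),
                   observed = obs,
                   ratio = if (obs > 0) mean(p[i]) / obs else NA_real_)
  }
  per_group <- purrr::map_dfr(seq_along(idx),
                              function(g) row_for(as.character(g), idx[[g]]))
  out <- dplyr::bind_rows(per_group, row_for("overall", seq_along(p)))
  class(out) <- c("decile_ratio", class(out))
  attr(out, "horizon") <- horizon
  out
}

#' Bootstrap comparison of two concordance indices
#'
#' Tests whether two risk scores for the same subjects differ in
#' discrimination: subjects are resampled with replacement, the difference
#' of the two Harrell C-indices is recomputed in each replicate, and a
#' two-sided p-value is read off the bootstrap distribution of the
#' difference. Scores that are monotone transforms of each other have a
#' difference of exactly zero in every replicate (p = 1).
#'
#' @inheritParams harrell_c
#' @param score_a,score_b The two score columns.
#' @param B Number of bootstrap replications.
#' @param seed Integer seed.
#' @return A one-row tibble: `c_a`, `c_b`, `difference`, `p.value`, `B`,
#'   `seed`.
#' @export
compare_c <- function(data, score_a, score_b, B = 1000, seed = 1,
                      time = time, event = event) {
  t <- rlang::eval_tidy(enquo(time), data)
  e <- rlang::eval_tidy(enquo(event), data)
  sa <- rlang::eval_tidy(enquo(score_a), data)
  sb <- rlang::eval_tidy(enquo(score_b), data)
  c_a <- concordance_index(t, e, sa)$c
  c_b <- concordance_index(t, e, sb)$c
  n <- length(t)
  set.seed(seed)
  diffs <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    concordance_index(t[idx], e[idx], sa[idx])$c -
      concordance_index(t[idx], e[idx], sb[idx])$c
  }, 0)
  p <- if (all(diffs == 0)) 1 else min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  tibble::tibble(c_a = c_a, c_b = c_b, difference = c_a - c_b,
                 p.value = p, B = B, seed = seed)
}
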