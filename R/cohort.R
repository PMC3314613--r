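#' Canonical cohort columns
#'
#' A cohort is an ordinary tibble with one row per participant and a set of
#' canonical columns. `cohort_columns()` lists them; `as_cohort()` validates
#' and coerces a data frame that already uses canonical names.
#'
#' Required columns: `id` (unique identifier), `age` (years), `sex`
#' (`"female"`/`"male"`), `total_cholesterol` and `hdl_cholesterol` (mg/dL),
#' `sbp` and `dbp` (mmHg), `diabetes` (0/1), `smoking`
#' (`"never"`/`"former"`/`"current"`), `time` (years to CHD event or
#' censoring, > 0) and `event` (1 = CHD event, 0 = censored; the strings
#' `"chd_event"`/`"censored"` are also accepted). Participants who die of
#' non-CHD causes enter as censored at the time of death.
#'
#' Optional columns (kept verbatim when present): `race`, `bmi`, `waist_cm`,
#' `glucose`, `creatinine`, `triglycerides`, `alcohol`, `physical_activity`,
#' `aspirin`, `prevalent_cvd`.
#'
#' @return `cohort_columns()` returns a list with elements `required` and
#'   `optional`; `as_cohort()` returns a validated tibble carrying a
#'   `horizon` attribute.
#' @export
cohort_columns <- function() {
  list(
    required = c("id", "age", "sex", "total_cholesterol", "hdl_cholesterol",
                 "sbp", "dbp", "diabetes", "smoking", "time", "event"),
    optional = c("race", "bmi", "waist_cm", "glucose", "creatinine",
                 "triglycerides", "alcohol", "physical_activity", "aspirin",
                 "prevalent_cvd")
  )
}

risk_factor_columns <- function() {
  c("age", "sex", "total_cholesterol", "hdl_cholesterol",
    "sbp", "dbp", "diabetes", "smoking")
}

#' @rdname cohort_columns
#' @param data A data frame with canonical column names.
#' @param horizon Analysis horizon in years attached to the table as an
#'   attribute (default 7.5).
#' @export
as_cohort <- function(data, horizon = 7.5) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (horizon <= 0) abort("`horizon` must be > 0.")
  cols <- cohort_columns()
  missing_cols <- setdiff(cols$required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required cohort column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out$id <- as.character(out$id)
  if (anyNA(out$id)) abort("`id` must not be missing.")
  if (anyDuplicated(out$id) > 0) {
    dup <- unique(out$id[duplicated(out$id)])
    abort(sprintf("Duplicate id(s): %s.", paste(head(dup, 5), collapse = ", ")))
  }

  num_cols <- c("age", "total_cholesterol", "hdl_cholesterol", "sbp", "dbp",
                "time", intersect(c("bmi", "waist_cm", "glucose", "creatinine",
                                    "triglycerides"), names(out)))
  for (col in num_cols) out[[col]] <- parse_cohort_numeric(out[[col]], col, out$id)

  out$sex <- parse_cohort_level(out$sex, "sex", c("female", "male"), out$id)
  out$smoking <- parse_cohort_level(out$smoking, "smoking",
                                    c("never", "former", "current"), out$id)
  out$diabetes <- parse_cohort_indicator(out$diabetes, "diabetes", out$id)
  out$event <- parse_cohort_event(out$event, out$id)
  for (col in intersect(c("aspirin", "prevalent_cvd"), names(out))) {
    out[[col]] <- parse_cohort_indicator(out[[col]], col, out$id)
  }
  if ("race" %in% names(out)) {
    out$race <- parse_cohort_level(out$race, "race",
                                   c("white", "black", "other"), out$id)
  }

  bad <- !is.na(out$time) & out$time <= 0
  if (anyNA(out$time) || any(bad)) {
    abort(sprintf("`time` must be present and > 0 for every record (first offender: id %s).",
                  out$id[which(is.na(out$time) | bad)[1]]))
  }
  if (anyNA(out$event)) {
    abort(sprintf("`event` must be present for every record (first offender: id %s).",
                  out$id[which(is.na(out$event))[1]]))
  }
  for (col in c("total_cholesterol", "hdl_cholesterol", "sbp", "dbp")) {
    bad <- !is.na(out[[col]]) & out[[col]] <= 0
    if (any(bad)) {
      abort(sprintf("`%s` must be strictly positive (id %s).",
                    col, out$id[which(bad)[1]]))
    }
  }
  attr(out, "horizon") <- horizon
  out
}

parse_cohort_numeric <- function(x, col, id) {
  raw <- trimws(as.character(x))
  raw[raw %in% c("", "NA")] <- NA_character_
  val <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & is.na(val)
  if (any(bad)) {
    abort(sprintf("Unparseable numeric in `%s` for id %s (value \"%s\").",
                  col, id[which(bad)[1]], raw[which(bad)[1]]))
  }
  val
}

parse_cohort_level <- function(x, col, levels, id) {
  raw <- tolower(trimws(as.character(x)))
  raw[raw %in% c("", "na")] <- NA_character_
  bad <- !is.na(raw) & !raw %in% levels
  if (any(bad)) {
    abort(sprintf("Invalid `%s` value \"%s\" for id %s (expected %s).",
                  col, raw[which(bad)[1]], id[which(bad)[1]],
                  paste(levels, collapse = "/")))
  }
  factor(raw, levels = levels)
}

parse_cohort_indicator <- function(x, col, id) {
  if (is.logical(x)) return(as.integer(x))
  raw <- tolower(trimws(as.character(x)))
  raw[raw %in% c("", "na")] <- NA_character_
  val <- dplyr::case_when(
    raw %in% c("1", "true", "yes") ~ 1L,
    raw %in% c("0", "false", "no") ~ 0L,
    TRUE ~ NA_integer_
  )
  bad <- !is.na(raw) & is.na(val)
  if (any(bad)) {
    abort(sprintf("Invalid indicator value \"%s\" in `%s` for id %s.",
                  raw[which(bad)[1]], col, id[which(bad)[1]]))
  }
  val
}

parse_cohort_event <- function(x, id) {
  raw <- tolower(trimws(as.character(x)))
  raw[raw %in% c("", "na")] <- NA_character_
  val <- dplyr::case_when(
    raw %in% c("1", "chd_event", "event", "true") ~ 1L,
    raw %in% c("0", "censored", "false") ~ 0L,
    TRUE ~ NA_integer_
  )
  bad <- !is.na(raw) & is.na(val)
  if (any(bad)) {
    abort(sprintf("Invalid `event` value \"%s\" for id %s.",
                  raw[which(bad)[1]], id[which(bad)[1]]))
  }
  val
}

#' Read and write person-level cohort files
#'
#' `read_cohort()` reads a CSV cohort file, optionally renaming columns via a
#' schema, and returns a validated cohort tibble (see [cohort_columns()]).
#' `write_cohort()` writes one back; `write_cohort()` then `read_cohort()`
#' is the identity on valid tables.
#'
#' @param path Path to a CSV file.
#' @param schema Optional mapping from canonical column names to the names
#'   used in the file: a named character vector
#'   (e.g. `c(sbp = "SystolicBP")`), or the path to a JSON file holding such
#'   a map.
#' @param horizon Analysis horizon in years (default 7.5).
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, schema = NULL, horizon = 7.5) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    if (is.character(schema) && is.null(names(schema)) && length(schema) == 1) {
      schema <- unlist(jsonlite::read_json(schema, simplifyVector = TRUE))
    }
    schema <- unlist(schema)
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      abort(sprintf("Schema maps to column(s) absent from the file: %s.",
                    paste(missing_src, collapse = ", ")))
    }
    names(raw)[match(unname(schema), names(raw))] <- names(schema)
  }
  keep <- intersect(names(raw), unlist(cohort_columns()))
  as_cohort(raw[keep], horizon = horizon)
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Apply the analysis inclusion rules
#'
#' Drops records with missing data for any traditional cardiovascular risk
#' factor (age, sex, total and HDL cholesterol, systolic and diastolic blood
#' pressure, diabetes, smoking). When a `prevalent_cvd` column is present,
#' records flagged 1 are dropped first (pre-existing cardiovascular disease).
#' Each dropped record is counted under a single reason: `prevalent_cvd` if
#' flagged, otherwise `missing_<field>` for the first missing field in
#' canonical order, so logged drops sum to the number of rows removed.
#'
#' The exclusion log is attached as an attribute; retrieve it with
#' `exclusion_log()`. The operation is idempotent.
#'
#' @param cohort A cohort tibble.
#' @return The filtered cohort tibble with an `exclusion_log` attribute
#'   (a tibble with columns `reason` and `n`).
#' @export
apply_exclusions <- function(cohort) {
  horizon <- attr(cohort, "horizon") %||% 7.5
  reason <- rep(NA_character_, nrow(cohort))
  if ("prevalent_cvd" %in% names(cohort)) {
    reason[!is.na(cohort$prevalent_cvd) & cohort$prevalent_cvd == 1] <- "prevalent_cvd"
  }
  for (col in risk_factor_columns()) {
    hit <- is.na(reason) & is.na(cohort[[col]])
    reason[hit] <- paste0("missing_", col)
  }
  log <- tibble::tibble(reason = reason[!is.na(reason)]) |>
    dplyr::count(.data$reason, name = "n")
  out <- cohort[is.na(reason), , drop = FALSE]
  attr(out, "horizon") <- horizon
  attr(out, "exclusion_log") <- log
  out
}

#' @rdname apply_exclusions
#' @param x A cohort returned by `apply_exclusions()`.
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusion_log") %||%
    tibble::tibble(reason = character(), n = integer())
}

#' @rdname cohort_columns
#' @param x A cohort tibble.
#' @export
cohort_horizon <- function(x) attr(x, "horizon") %||% 7.5
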