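#' The ordinal levels-of-evidence scale for systematic error
#'
#' Ten categories ordering study designs by their risk of systematic error
#' (bias), from meta-analyses of randomized trials with low risk of bias
#' (level 1a, rank 1) down to expert opinion (level 5, rank 10). Lower rank
#' means lower risk of systematic error.
#'
#' @return A tibble with columns `label`, `rank`, `description`.
#' @examples
#' evidence_levels()
#' @export
evidence_levels <- function() {
  tibble(
    label = c("1a", "1b", "1c", "1d", "2a", "2b", "3a", "3b", "4", "5"),
    rank = 1:10,
    description = c(
      "Meta-analysis of randomized trials with low risk of bias",
      "Randomized trial with low risk of bias",
      "Meta-analysis of all randomized trials",
      "Randomized trial with high risk of bias",
      "Meta-analysis of cohort studies",
      "Cohort study",
      "Meta-analysis of case-control studies",
      "Case-control study",
      "Case-series",
      "Expert opinion"))
}

#' Parse evidence-level labels
#'
#' Matches labels case-insensitively after trimming whitespace against the
#' ten categories of [evidence_levels()].
#'
#' @param x Character vector of level labels (e.g. `"1a"`, `"2b"`).
#' @return An ordered factor with the ten labels in rank order.
#' @examples
#' parse_level(c("1a", " 2B "))
#' @export
parse_level <- function(x) {
  lv <- evidence_levels()
  cleaned <- tolower(trimws(as.character(x)))
  bad <- !is.na(cleaned) & !(cleaned %in% lv$label)
  if (any(bad)) {
    stop_em("unknown_level", sprintf(
      "Unknown evidence level%s %s; valid labels are %s.",
      if (sum(bad) > 1) "s" else "",
      paste(unique(x[bad]), collapse = ", "),
      paste(lv$label, collapse = ", ")))
  }
  factor(cleaned, levels = lv$label, ordered = TRUE)
}

#' Integer rank of an evidence level (1 = lowest risk of bias)
#'
#' @inheritParams parse_level
#' @return An integer vector of ranks 1-10.
#' @export
level_rank <- function(x) {
  as.integer(parse_level(x))
}

#' Named bands for the risk of random error
#'
#' The magnitude of a standard error of a log effect measure is summarised
#' in five named bands partitioning `[0, Inf)`: ignorable `[0, 0.10)`, small
#' `[0.10, 0.20)`, moderate `[0.20, 0.30)`, substantial `[0.30, 0.50)`, high
#' `[0.50, Inf)`. Intervals are left-closed, so a boundary SE belongs to the
#' upper band (an SE of exactly 0.10 carries a small, not ignorable, risk).
#'
#' @return A tibble with columns `band`, `lower`, `upper`.
#' @examples
#' risk_bands()
#' @export
risk_bands <- function() {
  tibble(
    band = c("ignorable", "small", "moderate", "substantial", "high"),
    lower = c(0, 0.10, 0.20, 0.30, 0.50),
    upper = c(0.10, 0.20, 0.30, 0.50, Inf))
}

#' Classify standard errors into risk-of-random-error bands
#'
#' @param se Non-negative finite numeric vector of standard errors of log
#'   effect measures; `NA` propagates.
#' @param bands Band definition tibble as returned by [risk_bands()]
#'   (columns `band`, `lower`, `upper`; must partition `[0, Inf)`).
#' @return An ordered factor with the band names as levels.
#' @examples
#' classify_random_error(c(0.02, 0.12, 0.28, 0.43, 0.78))
#' @export
classify_random_error <- function(se, bands = risk_bands()) {
  if (any(!is.na(se) & (!is.finite(se) | se < 0))) {
    stop_em("domain", "`se` must be non-negative and finite.")
  }
  need_columns(bands, c("band", "lower", "upper"), "`bands`")
  if (bands$lower[1] != 0 || !is.infinite(bands$upper[nrow(bands)]) ||
      any(bands$lower[-1] != bands$upper[-nrow(bands)])) {
    stop_em("config", "`bands` must partition [0, Inf) with contiguous intervals.")
  }
  cut(se, breaks = c(bands$lower, Inf), labels = bands$band,
      right = FALSE, ordered_result = TRUE)
}

#' Construct an outcome specification table
#'
#' Outcomes are graded by importance to patients on a 1-9 scale (9 = most
#' critical; mortality). Scores 7-9 are critical for decision making, 4-6
#' important but not critical, 1-3 not important. `adverse` records whether
#' fewer events is better (default `TRUE`), which fixes the benefit/harm
#' reading of ratio estimates for that outcome.
#'
#' @param name Character vector of outcome names.
#' @param grade_score Integer importance scores in 1-9.
#' @param adverse Logical, recycled.
#' @param display_order Integer tie-break for equal scores; defaults to the
#'   order given.
#' @return A tibble with columns `outcome`, `grade_score`, `grade_category`,
#'   `adverse`, `display_order`.
#' @examples
#' outcome_specs(c("all-cause mortality", "non-fatal stroke"), c(9, 7))
#' @export
outcome_specs <- function(name, grade_score, adverse = TRUE,
                          display_order = seq_along(name)) {
  if (any(is.na(grade_score)) || any(grade_score < 1) || any(grade_score > 9) ||
      any(grade_score != trunc(grade_score))) {
    stop_em("domain", "`grade_score` must be whole numbers in 1..9.")
  }
  if (anyDuplicated(name)) {
    stop_em("domain", "Outcome names must be unique.")
  }
  tibble(
    outcome = as.character(name),
    grade_score = as.integer(grade_score),
    grade_category = factor(
      ifelse(grade_score >= 7, "critical",
      ifelse(grade_score >= 4, "important", "not_important")),
      levels = c("critical", "important", "not_important"), ordered = TRUE),
    adverse = rep_len(as.logical(adverse), length(name)),
    display_order = as.integer(rep_len(display_order, length(name))))
}

#' Order outcomes by importance
#'
#' Sorts an outcome specification by descending grade score (most critical
#' first); ties are broken by `display_order`, then name. Outcomes in
#' different importance categories are never interchangeable (mortality
#' always precedes, say, length of hospital stay), which the descending
#' score ordering guarantees.
#'
#' @param specs An outcome specification tibble from [outcome_specs()].
#' @return The specification tibble, reordered.
#' @export
order_outcomes <- function(specs) {
  need_columns(specs, c("outcome", "grade_score"), "`specs`")
  if (nrow(specs) == 0) stop_em("domain", "`specs` must contain at least one outcome.")
  ord <- specs
  if (!"display_order" %in% names(ord)) ord$display_order <- seq_len(nrow(ord))
  arrange(ord, dplyr::desc(.data$grade_score), .data$display_order, .data$outcome)
}

#' Best available evidence for one outcome
#'
#' Among the study records with a computable standard error for the given
#' outcome, returns the record with the best (lowest-rank) evidence level;
#' ties on level are broken by the smaller SE, then by study id. Cells coded
#' Z (zero events) or N (not reported) are never selected.
#'
#' @param records A study-record tibble (see [read_study_table()]); standard
#'   errors are computed first via [compute_estimates()] if absent.
#' @param outcome Name of the outcome to consider.
#' @param ... Passed on to [compute_estimates()] when augmentation is needed.
#' @return A one-row tibble with at least `study_id`, `level`, `level_rank`,
#'   `outcome`, `se_ln`, `band`.
#' @examples
#' ex2 <- load_fixture("example2")
#' best_available(ex2$records, "all-cause mortality")
#' @export
best_available <- function(records, outcome, ...) {
  aug <- ensure_estimates(records, ...)
  cand <- aug |>
    filter(.data$outcome == .env$outcome, is.finite(.data$se_ln))
  if (nrow(cand) == 0) {
    stop_em("no_evidence", sprintf(
      "No record has a computable SE for outcome '%s'.", outcome))
  }
  cand |>
    arrange(.data$level_rank, .data$se_ln, .data$study_id) |>
    slice(1)
}
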