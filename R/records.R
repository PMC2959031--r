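#' Compute effect estimates and standard errors for a study table
#'
#' The workhorse augmentation step: given a study-record tibble with one row
#' per (study, outcome), fills in the point estimate, the standard error of
#' its natural log, and how each was obtained. Each row must carry exactly
#' one of
#' \itemize{
#'   \item 2x2 counts `a`, `b`, `c`, `d` — the chosen `measure` and its SE
#'     are computed from the counts (`provenance "from_counts"`);
#'   \item `estimate`, `ci_lower`, `ci_upper` — the SE is back-calculated
#'     from the confidence interval via [se_from_ci()]
#'     (`provenance "from_ci"`);
#'   \item a reported `se` (optionally with a `direction` flag) — taken as
#'     is (`provenance "as_reported"`);
#'   \item a missingness `code`: `"Z"` (zero events, SE incalculable) or
#'     `"N"` (outcome not reported).
#' }
#' Count rows in which the SE formula would divide by zero (zero events in a
#' required margin) are demoted to code `"Z"` with a warning rather than
#' aborting the table.
#'
#' @param records A study-record tibble with columns `study_id`, `level`,
#'   `outcome` and the data columns above (missing data columns are treated
#'   as all-`NA`).
#' @param measure Effect measure for count rows: `"rr"` (relative risk,
#'   default) or `"peto"` (Peto odds ratio).
#' @param specs Optional outcome specification ([outcome_specs()]) supplying
#'   per-outcome `adverse` flags; by default all outcomes are treated as
#'   adverse events (ratio < 1 is benefit).
#' @param conf_level Confidence level assumed for `ci_lower`/`ci_upper`.
#' @param correct_zero Apply a 0.5 continuity correction to zero-event count
#'   rows instead of demoting them to code `"Z"`. Off by default.
#' @return The records as a tibble with added columns `level_rank`, `point`,
#'   `se_ln`, `provenance`, `direction`, `band`.
#' @examples
#' tibble::tibble(study_id = "t1", level = "1b", outcome = "death",
#'                a = 10, b = 90, c = 20, d = 80) |>
#'   compute_estimates()
#' @export
compute_estimates <- function(records, measure = c("rr", "peto"), specs = NULL,
                              conf_level = 0.95, correct_zero = FALSE) {
  measure <- match.arg(measure)
  need_columns(records, c("study_id", "level", "outcome"), "`records`")
  out <- as_tibble(records)
  for (col in c("a", "b", "c", "d")) {
    if (!col %in% names(out)) out[[col]] <- NA_integer_
  }
  for (col in c("estimate", "ci_lower", "ci_upper", "se")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  if (!"code" %in% names(out)) out$code <- NA_character_
  if (!"direction" %in% names(out)) out$direction <- NA_character_

  out$level_rank <- level_rank(out$level)

  has_counts <- !is.na(out$a) & !is.na(out$b) & !is.na(out$c) & !is.na(out$d)
  has_ci <- !is.na(out$estimate) & !is.na(out$ci_lower) & !is.na(out$ci_upper)
  has_se <- !is.na(out$se)
  has_code <- !is.na(out$code)
  n_sources <- has_counts + has_ci + has_se + has_code
  if (any(n_sources != 1)) {
    bad <- which(n_sources != 1)[1]
    stop_em("schema", sprintf(
      "Row %d (%s, %s): exactly one of counts {a,b,c,d}, {estimate, ci_lower, ci_upper}, a reported se, or a code must be given.",
      bad, out$study_id[bad], out$outcome[bad]))
  }
  if (any(has_code & !out$code %in% c("Z", "N"))) {
    stop_em("schema", "`code` must be 'Z' (zero events) or 'N' (not reported).")
  }

  point <- rep(NA_real_, nrow(out))
  se_ln <- rep(NA_real_, nrow(out))
  provenance <- rep(NA_character_, nrow(out))

  # count rows: demote incalculable tables to code Z unless corrected
  if (any(has_counts)) {
    idx <- which(has_counts)
    check_counts(out$a[idx], out$b[idx], out$c[idx], out$d[idx], "`records`")
    zero <- if (measure == "rr") {
      out$a[idx] == 0 | out$c[idx] == 0
    } else {
      out$a[idx] + out$c[idx] == 0
    }
    if (any(zero) && !correct_zero) {
      warn_em("zero_event", sprintf(
        "Zero events for %s: SE cannot be calculated; coded Z.",
        paste(sprintf("%s/%s", out$study_id[idx][zero], out$outcome[idx][zero]),
              collapse = ", ")))
      out$code[idx[zero]] <- "Z"
      idx <- idx[!zero]
    }
    if (length(idx)) {
      est <- if (measure == "rr") {
        relative_risk(out[idx, c("a", "b", "c", "d")], correct_zero = correct_zero)
      } else {
        peto_or(out[idx, c("a", "b", "c", "d")])
      }
      point[idx] <- est$point
      se_ln[idx] <- est$se_ln
      provenance[idx] <- "from_counts"
    }
  }

  if (any(has_ci)) {
    idx <- which(has_ci)
    point[idx] <- out$estimate[idx]
    se_ln[idx] <- se_from_ci(out$estimate[idx], out$ci_lower[idx],
                             out$ci_upper[idx], conf_level = conf_level)
    provenance[idx] <- "from_ci"
  }

  if (any(has_se)) {
    idx <- which(has_se)
    if (any(out$se[idx] < 0)) stop_em("domain", "Reported `se` must be non-negative.")
    se_ln[idx] <- out$se[idx]
    provenance[idx] <- "as_reported"
  }

  out$point <- point
  out$se_ln <- se_ln
  out$provenance <- provenance

  # benefit/harm direction: from the point estimate where available
  # (honouring per-outcome adverse flags), else from a reported flag
  adverse <- rep(TRUE, nrow(out))
  if (!is.null(specs) && "adverse" %in% names(specs)) {
    m <- match(out$outcome, specs$outcome)
    adverse <- ifelse(is.na(m), TRUE, specs$adverse[m])
  }
  dir_pt <- effect_direction(out$point, adverse = adverse)
  dir_flag <- tolower(trimws(out$direction))
  if (any(!is.na(dir_flag) & !dir_flag %in% c("benefit", "harm", "null"))) {
    stop_em("schema", "`direction` flags must be 'benefit', 'harm' or 'null'.")
  }
  out$direction <- factor(
    ifelse(!is.na(dir_pt), as.character(dir_pt), dir_flag),
    levels = levels(dir_pt))
  out$band <- classify_random_error(out$se_ln)
  out
}

# Augment only when the SE column is not already there.
ensure_estimates <- function(records, ...) {
  if (all(c("se_ln", "level_rank", "direction", "band") %in% names(records))) {
    return(as_tibble(records))
  }
  compute_estimates(records, ...)
}
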