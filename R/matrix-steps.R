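#' Matrix step I: studies ranked by systematic and random error
#'
#' For one outcome, collects every study with a computable standard error
#' into a scatter of evidence-level rank (systematic error) against SE
#' (random error). No omission cutoffs are applied at this step: even very
#' imprecise studies are shown, in contrast to step III.
#'
#' @inheritParams best_available
#' @param outcome Outcome to plot.
#' @return A tibble of class `em_step1` with columns `study_id`, `level`,
#'   `level_rank`, `outcome`, `se_ln`, `band`, sorted by rank then SE. Cells
#'   coded Z or N are excluded; an empty result is allowed.
#' @examples
#' ex1 <- load_fixture("example1")
#' build_step1(ex1$records, "all-cause mortality")
#' @export
build_step1 <- function(records, outcome, ...) {
  aug <- ensure_estimates(records, ...)
  pts <- aug |>
    filter(.data$outcome == .env$outcome, is.finite(.data$se_ln)) |>
    select(all_of(c("study_id", "level", "level_rank", "outcome", "se_ln", "band"))) |>
    arrange(.data$level_rank, .data$se_ln, .data$study_id)
  class(pts) <- c("em_step1", class(pts))
  pts
}

#' Matrix step II: studies in the outcome-importance by evidence-level grid
#'
#' Places each study in the cell (evidence level, outcome) for every outcome
#' it reports. Outcome columns follow the importance ordering of
#' [order_outcomes()]; level rows follow the levels-of-evidence ranking.
#' Cells coded Z (zero events) count as reported and are included; cells
#' coded N (not reported) are excluded.
#'
#' @inheritParams best_available
#' @param specs Outcome specification ([outcome_specs()]); if `NULL`, the
#'   outcomes are taken in order of first appearance with equal importance.
#' @return A tibble of class `em_step2` with one row per (study, level,
#'   outcome) placement: columns `outcome` (factor in importance order),
#'   `level` (factor in rank order), `level_rank`, `study_id`. Use
#'   [step2_grid()] for the wide cell view.
#' @export
build_step2 <- function(records, specs = NULL, ...) {
  aug <- ensure_estimates(records, ...)
  specs <- specs %||% default_specs(aug)
  specs <- order_outcomes(specs)
  placed <- aug |>
    filter(is.na(.data$code) | .data$code != "N") |>
    mutate(outcome = factor(.data$outcome, levels = specs$outcome),
           level = parse_level(.data$level)) |>
    select(all_of(c("outcome", "level", "level_rank", "study_id"))) |>
    arrange(.data$outcome, .data$level_rank, .data$study_id)
  if (any(is.na(placed$outcome))) {
    stop_em("schema", "Every outcome in `records` must appear in `specs`.")
  }
  class(placed) <- c("em_step2", class(placed))
  attr(placed, "specs") <- specs
  placed
}

#' Wide cell view of the step II grid
#'
#' @param placements The result of [build_step2()].
#' @return A tibble with one row per evidence level and one column per
#'   outcome, each cell a comma-separated list of the studies placed there.
#' @export
step2_grid <- function(placements) {
  placements |>
    as_tibble() |>
    group_by(.data$level, .data$outcome) |>
    summarise(studies = paste(.data$study_id, collapse = ", "), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "studies",
                       names_expand = TRUE, values_fill = "") |>
    arrange(.data$level)
}

#' Matrix step III: the benefit/harm Manhattan landscape
#'
#' Builds the bars of the three-dimensional "Manhattan" overview: one bar
#' per (study, outcome) estimate, grouped by outcome, positioned by evidence
#' level, with bar height decreasing linearly in the standard error,
#' \deqn{height = (c - \min(SE, c)) / c}
#' for SE cutoff `c` (default 1.0), so the tallest skyscrapers — the best
#' evidence — stand on the "upper west side". Bars are split into a benefit
#' panel and a harm panel by the direction of each estimate.
#'
#' Omission rules: bars whose evidence level is worse than `level_cutoff`
#' (default `"2b"`) or whose SE is at or beyond `se_cutoff` (height zero) are
#' dropped, as are cells without a computable SE (codes Z and N). Estimates
#' exactly at the null belong to neither panel and are dropped with a
#' message.
#'
#' @inheritParams build_step2
#' @param se_cutoff Positive SE at and beyond which bars are omitted.
#' @param level_cutoff Worst evidence level retained.
#' @return A tibble of class `em_step3` with columns `panel`
#'   (`benefit`/`harm`), `outcome`, `study_id`, `level`, `level_rank`,
#'   `se_ln`, `band`, `height`; within a panel bars are grouped by outcome
#'   then sorted by level rank and SE.
#' @examples
#' ex1 <- load_fixture("example1")
#' build_step3(ex1$records, ex1$specs)
#' @export
build_step3 <- function(records, specs = NULL, se_cutoff = 1.0,
                        level_cutoff = "2b", ...) {
  if (!is.numeric(se_cutoff) || length(se_cutoff) != 1 || !is.finite(se_cutoff) ||
      se_cutoff <= 0) {
    stop_em("domain", "`se_cutoff` must be a single positive number.")
  }
  max_rank <- level_rank(level_cutoff)
  aug <- ensure_estimates(records, ...)
  specs <- order_outcomes(specs %||% default_specs(aug))

  usable <- aug |> filter(is.finite(.data$se_ln), !is.na(.data$direction))
  nulls <- usable |> filter(.data$direction == "null")
  if (nrow(nulls) > 0) {
    inform(sprintf(
      "%d estimate(s) exactly at the null assigned to neither panel: %s.",
      nrow(nulls),
      paste(sprintf("%s/%s", nulls$study_id, nulls$outcome), collapse = ", ")))
  }
  bars <- usable |>
    filter(.data$direction != "null",
           .data$level_rank <= max_rank,
           .data$se_ln < se_cutoff) |>
    mutate(panel = factor(as.character(.data$direction),
                          levels = c("benefit", "harm")),
           outcome = factor(.data$outcome, levels = specs$outcome),
           level = parse_level(.data$level),
           height = (se_cutoff - pmin(.data$se_ln, se_cutoff)) / se_cutoff) |>
    select(all_of(c("panel", "outcome", "study_id", "level", "level_rank",
                    "se_ln", "band", "height"))) |>
    arrange(.data$panel, .data$outcome, .data$level_rank, .data$se_ln)
  class(bars) <- c("em_step3", class(bars))
  attr(bars, "se_cutoff") <- se_cutoff
  attr(bars, "level_cutoff") <- level_cutoff
  bars
}

#' Matrix step IV: size and direction of the intervention effect
#'
#' The last step is only meaningful for outcomes whose best available
#' evidence is internally valid, so each outcome is first screened on both
#' error dimensions: the best available record must sit at or above
#' `max_level` and within `max_band` of random error. Outcomes that pass are
#' summarised by their best-available estimate, its direction, and — when
#' the record carries 2x2 counts — the absolute risk reduction and number
#' needed to treat. Outcomes that fail are reported as insufficient
#' evidence, with the failing dimension(s) named.
#'
#' @inheritParams build_step2
#' @param max_level Worst acceptable evidence level (default `"2b"`).
#' @param max_band Worst acceptable risk-of-random-error band
#'   (default `"moderate"`).
#' @return A tibble of class `em_step4`, one row per outcome: `outcome`,
#'   `status` (`"ok"` or `"insufficient_evidence"`), `reasons`, `study_id`,
#'   `level`, `se_ln`, `band`, `point`, `direction`, `p1`, `p2`, `arr`,
#'   `nnt`, `nnt_display`.
#' @examples
#' ex2 <- load_fixture("example2")
#' build_step4(ex2$records, ex2$specs)
#' @export
build_step4 <- function(records, specs = NULL, max_level = "2b",
                        max_band = "moderate", ...) {
  aug <- ensure_estimates(records, ...)
  specs <- order_outcomes(specs %||% default_specs(aug))
  max_rank <- level_rank(max_level)
  band_names <- risk_bands()$band
  if (!max_band %in% band_names) {
    stop_em("domain", sprintf("`max_band` must be one of %s.",
                              paste(band_names, collapse = ", ")))
  }
  max_band_i <- match(max_band, band_names)

  empty_row <- function(outcome, reasons, best = NULL) {
    tibble(
      outcome = outcome, status = "insufficient_evidence",
      reasons = paste(reasons, collapse = ", "),
      study_id = if (is.null(best)) NA_character_ else best$study_id,
      level = if (is.null(best)) NA_character_ else as.character(best$level),
      se_ln = if (is.null(best)) NA_real_ else best$se_ln,
      band = if (is.null(best)) NA_character_ else as.character(best$band),
      point = NA_real_, direction = NA_character_,
      p1 = NA_real_, p2 = NA_real_, arr = NA_real_, nnt = NA_real_,
      nnt_display = NA_integer_)
  }

  rows <- purrr::map(specs$outcome, function(oc) {
    best <- tryCatch(best_available(aug, oc),
                     em_no_evidence = function(e) NULL)
    if (is.null(best)) return(empty_row(oc, "no computable evidence"))
    fails <- character()
    if (best$level_rank > max_rank) fails <- c(fails, "systematic error")
    if (match(as.character(best$band), band_names) > max_band_i) {
      fails <- c(fails, "random error")
    }
    if (length(fails)) return(empty_row(oc, fails, best))
    has_counts <- all(!is.na(c(best$a, best$b, best$c, best$d)))
    rd <- if (has_counts) {
      risk_difference_nnt(best[, c("a", "b", "c", "d")], allow_null = TRUE)
    } else NULL
    tibble(
      outcome = oc, status = "ok", reasons = "",
      study_id = best$study_id, level = as.character(best$level),
      se_ln = best$se_ln, band = as.character(best$band),
      point = best$point, direction = as.character(best$direction),
      p1 = if (has_counts) rd$p1 else NA_real_,
      p2 = if (has_counts) rd$p2 else NA_real_,
      arr = if (has_counts) rd$arr else NA_real_,
      nnt = if (has_counts) rd$nnt else NA_real_,
      nnt_display = if (has_counts) rd$nnt_display else NA_integer_)
  })
  out <- bind_rows(rows)
  class(out) <- c("em_step4", class(out))
  out
}

# equal-importance fallback specification from the records themselves
default_specs <- function(records) {
  ocs <- unique(records$outcome)
  outcome_specs(ocs, grade_score = rep(9L, length(ocs)))
}

#' Serialize step III panels to a plain list
#'
#' The documented JSON structure: `se_cutoff`, `level_cutoff`, and a
#' `panels` object mapping `benefit`/`harm` to outcome-keyed arrays of bars.
#'
#' @param bars The result of [build_step3()].
#' @return A nested list, ready for [jsonlite::toJSON()].
#' @export
serialize_step3 <- function(bars) {
  one_panel <- function(p) {
    sub <- bars |> as_tibble() |> filter(.data$panel == p)
    ocs <- as.character(unique(sub$outcome))
    stats::setNames(lapply(ocs, function(oc) {
      sub |>
        filter(.data$outcome == oc) |>
        mutate(level = as.character(.data$level),
               band = as.character(.data$band)) |>
        select(all_of(c("study_id", "level", "level_rank", "se_ln", "band",
                        "height")))
    }), ocs)
  }
  list(se_cutoff = attr(bars, "se_cutoff"),
       level_cutoff = attr(bars, "level_cutoff"),
       panels = list(benefit = one_panel("benefit"), harm = one_panel("harm")))
}
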