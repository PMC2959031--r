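#' Read a study table from CSV or JSON
#'
#' A study table has one row per (study, outcome) with columns `study_id`,
#' `level`, `outcome` and exactly one data source per row: the 2x2 counts
#' `a`, `b`, `c`, `d`; a reported `estimate` with `ci_lower` and `ci_upper`;
#' a reported `se` (optionally with a benefit/harm `direction` flag); or a
#' missingness `code` (`Z` = zero events, `N` = not reported). Decimal
#' commas (`"0,28"`) are normalized to decimal points on read; `#` lines are
#' comments. Row order is preserved and evidence levels are validated
#' against [evidence_levels()].
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A study-record tibble ready for [compute_estimates()].
#' @seealso [write_study_table()], [load_fixture()]
#' @export
read_study_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_em("schema", sprintf("File '%s' does not exist.", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- if (format == "csv") {
    if (length(readLines(path, n = 1, warn = FALSE)) == 0) {
      stop_em("schema", sprintf("File '%s' is empty (no header).", path))
    }
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    comment = "#", progress = FALSE)
  } else {
    df <- jsonlite::fromJSON(path)
    if (is.list(df) && !is.data.frame(df) && !is.null(df$records)) df <- df$records
    as_tibble(df) |> mutate(across(dplyr::everything(), as.character))
  }
  need_columns(raw, c("study_id", "level", "outcome"), sprintf("'%s'", path))
  rec <- normalize_records(raw)
  validate_records(rec, path)
  rec
}

# canonical column set, types, and decimal-comma normalization
record_columns <- function() {
  c("study_id", "level", "outcome", "a", "b", "c", "d",
    "estimate", "ci_lower", "ci_upper", "se", "direction", "code")
}

normalize_records <- function(df) {
  out <- as_tibble(df)
  for (col in record_columns()) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out <- out[, record_columns()]
  num <- function(x) {
    x <- gsub(",", ".", trimws(as.character(x)), fixed = TRUE)
    x[x == ""] <- NA_character_
    as.numeric(x)
  }
  chr <- function(x) {
    x <- trimws(as.character(x))
    x[x == ""] <- NA_character_
    x
  }
  out |>
    mutate(across(all_of(c("study_id", "level", "outcome", "direction", "code")), chr),
           across(all_of(c("a", "b", "c", "d")), \(x) as.integer(num(x))),
           across(all_of(c("estimate", "ci_lower", "ci_upper", "se")), num))
}

validate_records <- function(rec, path = "study table") {
  has_counts <- !is.na(rec$a) & !is.na(rec$b) & !is.na(rec$c) & !is.na(rec$d)
  partial <- (!is.na(rec$a) | !is.na(rec$b) | !is.na(rec$c) | !is.na(rec$d)) & !has_counts
  has_ci <- !is.na(rec$estimate) & !is.na(rec$ci_lower) & !is.na(rec$ci_upper)
  partial_ci <- (!is.na(rec$estimate) | !is.na(rec$ci_lower) | !is.na(rec$ci_upper)) & !has_ci
  has_se <- !is.na(rec$se)
  has_code <- !is.na(rec$code)
  n_src <- has_counts + has_ci + has_se + has_code
  bad <- which(n_src != 1 | partial | partial_ci)
  if (length(bad)) {
    stop_em("schema", sprintf(
      "Row %d of %s: each row needs exactly one of counts {a,b,c,d}, {estimate, ci_lower, ci_upper}, a reported se, or a code.",
      bad[1], path))
  }
  if (any(has_code & !rec$code %in% c("Z", "N"))) {
    i <- which(has_code & !rec$code %in% c("Z", "N"))[1]
    stop_em("schema", sprintf(
      "Row %d of %s: code '%s' is not one of Z, N.", i, path, rec$code[i]))
  }
  withCallingHandlers(
    parse_level(rec$level),
    em_unknown_level = function(e) {
      stop_em("unknown_level",
              sprintf("In %s: %s", path, conditionMessage(e)))
    })
  invisible(rec)
}

#' Write a study table to CSV or JSON
#'
#' Inverse of [read_study_table()]: writing then reading a valid record
#' tibble reproduces it exactly (both formats).
#'
#' @param records A study-record tibble.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  rec <- normalize_records(records)[, record_columns()]
  if (format == "csv") {
    readr::write_csv(rec, path, na = "", progress = FALSE)
  } else {
    jsonlite::write_json(rec, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Packaged worked examples
#'
#' Two study tables shipped with the package:
#' \describe{
#'   \item{`example1`}{Peri-operative beta-blockade versus placebo for major
#'     non-cardiac surgery: 10 records (studies at levels 1a-5) by four
#'     adverse outcomes, graded all-cause mortality (9) > cardiovascular
#'     mortality (8) > non-fatal myocardial infarction (7) > non-fatal
#'     stroke (7).}
#'   \item{`example2`}{Class 1a antiarrhythmics for maintaining sinus rhythm
#'     after cardioversion of atrial fibrillation: 9 records on all-cause
#'     mortality, including a meta-analysis reported as OR 2.39
#'     (95% CI 1.03-5.59) whose SE is back-calculated on load.}
#' }
#' The underlying 2x2 counts of these published studies are not available,
#' so cells carry reported standard errors (provenance `"as_reported"`)
#' with benefit/harm direction flags taken from the published conclusions;
#' see the comments in the fixture CSVs under `inst/extdata/`.
#'
#' @param name `"example1"` or `"example2"`.
#' @return A list with elements `records` (study-record tibble) and `specs`
#'   (outcome specification tibble).
#' @examples
#' ex1 <- load_fixture("example1")
#' dplyr::count(ex1$records, level)
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("example1", "example2")) {
    stop_em("unknown_fixture",
      "Unknown fixture; available fixtures are 'example1' and 'example2'.")
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "errormatrix",
                      mustWork = TRUE)
  records <- read_study_table(path, format = "csv")
  specs <- if (name == "example1") {
    outcome_specs(
      c("all-cause mortality", "cardiovascular mortality",
        "non-fatal myocardial infarction", "non-fatal stroke"),
      grade_score = c(9L, 8L, 7L, 7L))
  } else {
    outcome_specs("all-cause mortality", grade_score = 9L)
  }
  list(records = records, specs = specs)
}

#' Read an analysis configuration from YAML
#'
#' Optional keys: `bands` (list of `band`/`lower`/`upper` entries replacing
#' [risk_bands()]), `se_cutoff`, `level_cutoff`, `outcomes` (list of
#' `name`/`grade_score`/`adverse`/`display_order` entries) and `colors`
#' (outcome-name to colour map for the Manhattan figure). Missing keys fall
#' back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `bands`, `se_cutoff`, `level_cutoff`,
#'   `specs`, `colors` (unspecified entries `NULL` except `bands` and the
#'   cutoffs, which default).
#' @export
read_matrix_config <- function(path) {
  if (!file.exists(path)) {
    stop_em("config", sprintf("Config file '%s' does not exist.", path))
  }
  cfg <- yaml::read_yaml(path)
  bands <- if (!is.null(cfg$bands)) {
    b <- bind_rows(lapply(cfg$bands, as_tibble))
    need_columns(b, c("band", "lower", "upper"), "`bands` config")
    b$upper[is.na(b$upper)] <- Inf
    b
  } else {
    risk_bands()
  }
  specs <- if (!is.null(cfg$outcomes)) {
    oc <- cfg$outcomes
    outcome_specs(
      purrr::map_chr(oc, "name"),
      purrr::map_int(oc, \(x) as.integer(x$grade_score)),
      adverse = purrr::map_lgl(oc, \(x) isTRUE(x$adverse %||% TRUE)),
      display_order = purrr::map_int(
        seq_along(oc), \(i) as.integer(oc[[i]]$display_order %||% i)))
  } else NULL
  list(bands = bands,
       se_cutoff = cfg$se_cutoff %||% 1.0,
       level_cutoff = cfg$level_cutoff %||% "2b",
       specs = specs,
       colors = unlist(cfg$colors) %||% NULL)
}
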