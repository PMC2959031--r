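#' @importFrom rlang abort warn inform .data .env :=
#' @importFrom dplyr mutate filter arrange select bind_cols bind_rows left_join
#'   group_by summarise ungroup row_number across all_of distinct slice pull
#'   n relocate rename if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats qnorm rbinom runif
NULL

# classed condition helpers -------------------------------------------------

stop_em <- function(class, message, ...) {
  abort(message, class = c(paste0("em_", class), "em_error"), ...)
}

warn_em <- function(class, message, ...) {
  warn(message, class = c(paste0("em_", class), "em_warning"), ...)
}

# count validation ----------------------------------------------------------

check_counts <- function(a, b, c, d, call_name = "table") {
  cnt <- list(a = a, b = b, c = c, d = d)
  for (nm in names(cnt)) {
    x <- cnt[[nm]]
    if (any(is.na(x)) || any(!is.finite(x)) || any(x < 0) || any(x != trunc(x))) {
      stop_em("domain", sprintf(
        "`%s` must contain non-negative integer counts in %s.", nm, call_name))
    }
  }
  n1 <- a + b
  n2 <- c + d
  if (any(n1 < 1) || any(n2 < 1)) {
    stop_em("domain", "Each arm must contain at least one patient (n1 >= 1 and n2 >= 1).")
  }
  invisible(TRUE)
}

need_columns <- function(data, cols, what = "data") {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop_em("schema", sprintf(
      "%s is missing required column%s: %s.",
      what, if (length(miss) > 1) "s" else "", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
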