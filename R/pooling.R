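#' Per-trial components of the pooled estimators
#'
#' For a set of 2x2 tables, computes the per-trial Mantel-Haenszel
#' components
#' \deqn{P_i = (n_{1i} n_{2i} (a_i + c_i) - a_i c_i N_i) / N_i^2,\quad
#'       R_i = a_i n_{2i} / N_i,\quad S_i = c_i n_{1i} / N_i,}
#' and the Peto observed-minus-expected `Z_i` and hypergeometric variance
#' `V_i`. The pooled estimators are built from the plain sums of these
#' columns. Trials with no events at all (`a + c = 0`) contribute zero to
#' every sum and are dropped with a warning.
#'
#' @param data A data frame of trials with columns `a`, `b`, `c`, `d`
#'   (and optionally `study_id`; labels must be unique).
#' @return The trials as a tibble with added columns `P`, `R`, `S`, `Z`, `V`.
#' @export
pool_components <- function(data) {
  need_columns(data, c("a", "b", "c", "d"), "`data`")
  if (nrow(data) == 0) stop_em("domain", "At least one trial is required.")
  if ("study_id" %in% names(data) && anyDuplicated(data$study_id)) {
    stop_em("domain", "Trial labels in `study_id` must be unique.")
  }
  check_counts(data$a, data$b, data$c, data$d, "`data`")
  none <- data$a + data$c == 0
  if (any(none)) {
    warn_em("zero_event", sprintf(
      "%d trial(s) with zero total events dropped from the pool.", sum(none)))
    data <- data[!none, , drop = FALSE]
    if (nrow(data) == 0) stop_em("no_events", "All trials have zero events.")
  }
  a <- as.numeric(data$a); b <- as.numeric(data$b)
  c <- as.numeric(data$c); d <- as.numeric(data$d)
  n1 <- a + b; n2 <- c + d; N <- n1 + n2
  zv <- peto_zv(a, b, c, d)
  as_tibble(data) |>
    mutate(P = (n1 * n2 * (a + c) - a * c * N) / N^2,
           R = a * n2 / N, S = c * n1 / N, Z = zv$z, V = zv$v)
}

new_pooled <- function(measure, point, se_ln, components, dropped = 0L) {
  structure(
    list(measure = measure, point = point, se_ln = se_ln,
         k = nrow(components), components = components, dropped = dropped),
    class = "em_pooled")
}

#' Mantel-Haenszel pooled relative risk
#'
#' Fixed-effect pooling of 2x2 tables on the risk-ratio scale. The point
#' estimate is `R / S` and the standard error of its natural log is
#' \deqn{SE[\ln RR_{MH}] = \sqrt{P / (R S)}}
#' with `P`, `R`, `S` the sums of the per-trial components (see
#' [pool_components()]). For a single trial this SE reduces exactly to
#' [se_ln_rr()] of that table.
#'
#' @inheritParams pool_components
#' @return An object of class `em_pooled` with elements `measure`, `point`,
#'   `se_ln`, `k`, `components`; see [tidy.em_pooled()].
#' @examples
#' tibble::tibble(a = c(10, 8), b = c(90, 92), c = c(20, 19), d = c(80, 81)) |>
#'   mh_pooled_rr()
#' @export
mh_pooled_rr <- function(data) {
  comp <- pool_components(data)
  R <- sum(comp$R); S <- sum(comp$S); P <- sum(comp$P)
  if (R == 0 || S == 0) {
    stop_em("no_events",
      "No events in one arm across the whole trial set: pooled RR undefined.")
  }
  new_pooled("rr_mh", point = R / S, se_ln = sqrt(P / (R * S)), components = comp)
}

#' Pooled Peto odds ratio
#'
#' Fixed-effect one-step pooling on the Peto odds-ratio scale: the point
#' estimate is `exp(sum(Z_i) / sum(V_i))` and the standard error of its log
#' is `1 / sqrt(sum(V_i))`. Adding any trial with `V > 0` strictly decreases
#' this SE.
#'
#' @inheritParams pool_components
#' @return An object of class `em_pooled`.
#' @examples
#' tibble::tibble(a = c(5, 5), b = c(5, 5), c = c(5, 5), d = c(5, 5)) |>
#'   peto_pooled_or()
#' @export
peto_pooled_or <- function(data) {
  comp <- pool_components(data)
  sumZ <- sum(comp$Z); sumV <- sum(comp$V)
  if (sumV <= 0) {
    stop_em("no_events", "Total hypergeometric variance is zero: pooled Peto OR undefined.")
  }
  new_pooled("peto_or", point = exp(sumZ / sumV), se_ln = 1 / sqrt(sumV),
             components = comp)
}

#' @export
print.em_pooled <- function(x, ...) {
  lab <- c(rr_mh = "Mantel-Haenszel pooled relative risk",
           peto_or = "Pooled Peto odds ratio")[[x$measure]]
  cat(lab, sprintf("(%d trial%s)\n", x$k, if (x$k > 1) "s" else ""))
  cat(sprintf("  point estimate: %.4f\n  SE[ln]:        %.4f\n  risk band:     %s\n",
              x$point, x$se_ln, as.character(classify_random_error(x$se_ln))))
  invisible(x)
}

#' Tidy a pooled effect estimate
#'
#' @param x An `em_pooled` object.
#' @param ... Unused.
#' @return A one-row tibble with `measure`, `estimate`, `log_estimate`,
#'   `std_error_log`, `band`, `direction`.
#' @export
tidy.em_pooled <- function(x, ...) {
  tibble(measure = x$measure, estimate = x$point, log_estimate = log(x$point),
         std_error_log = x$se_ln, band = classify_random_error(x$se_ln),
         direction = effect_direction(x$point))
}

#' One-row summary of a pooled effect estimate
#'
#' @param x An `em_pooled` object.
#' @param ... Unused.
#' @return A one-row tibble with trial count and event totals.
#' @export
glance.em_pooled <- function(x, ...) {
  comp <- x$components
  tibble(k = x$k,
         n = sum(comp$a + comp$b + comp$c + comp$d),
         events_intervention = sum(comp$a),
         events_control = sum(comp$c))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
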