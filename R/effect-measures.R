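#' Standard error of the log relative risk from a 2x2 table
#'
#' For a two-arm study with `a` events among `n1 = a + b` intervention
#' patients and `c` events among `n2 = c + d` control patients, the standard
#' error of the natural log of the relative risk is
#' \deqn{SE[\ln RR] = \sqrt{1/a + 1/c - 1/n_1 - 1/n_2}.}
#' The radicand is non-negative for any valid table because `a <= n1` and
#' `c <= n2`. No continuity correction is applied by default: tables with
#' zero events in either arm raise a zero-event error, mirroring the
#' convention that the SE of outcomes with zero events cannot be calculated.
#'
#' @param a,b,c,d Non-negative integer vectors: events / non-events in the
#'   intervention arm (`a`, `b`) and control arm (`c`, `d`). Recycled to a
#'   common length.
#' @param correct_zero If `TRUE`, add 0.5 to all four cells of any table with
#'   `a == 0` or `c == 0` before computing (off by default).
#' @return A numeric vector of standard errors.
#' @examples
#' se_ln_rr(10, 90, 10, 90) # sqrt(0.18)
#' @export
se_ln_rr <- function(a, b, c, d, correct_zero = FALSE) {
  check_counts(a, b, c, d)
  zero <- a == 0 | c == 0
  if (any(zero)) {
    if (!correct_zero) {
      stop_em("zero_event",
        "Zero events in one arm: SE of ln(RR) cannot be calculated (code Z).",
        code = "Z")
    }
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
  }
  n1 <- a + b
  n2 <- c + d
  sqrt(pmax(1 / a + 1 / c - 1 / n1 - 1 / n2, 0))
}

#' Per-study relative risk with log-scale standard error
#'
#' Computes, row by row, the relative risk `RR = (a/n1) / (c/n2)` and the
#' standard error of its natural log (see [se_ln_rr()]) from the 2x2 counts
#' in `data`, and appends the result as new columns.
#'
#' @param data A data frame with integer columns `a`, `b`, `c`, `d`.
#' @inheritParams se_ln_rr
#' @return The input as a tibble with added columns `measure` (`"rr"`),
#'   `point`, `se_ln` and `provenance` (`"from_counts"`).
#' @examples
#' tibble::tibble(a = 10, b = 90, c = 20, d = 80) |> relative_risk()
#' @export
relative_risk <- function(data, correct_zero = FALSE) {
  need_columns(data, c("a", "b", "c", "d"), "`data`")
  a <- data$a; b <- data$b; c <- data$c; d <- data$d
  check_counts(a, b, c, d)
  se <- se_ln_rr(a, b, c, d, correct_zero = correct_zero)
  if (correct_zero) {
    zero <- a == 0 | c == 0
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
  }
  point <- (a / (a + b)) / (c / (c + d))
  as_tibble(data) |>
    mutate(measure = "rr", point = point, se_ln = se, provenance = "from_counts")
}

# Peto observed-minus-expected and hypergeometric variance for one stratum.
# Counts go to double first: the V numerator overflows 32-bit integers.
peto_zv <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n1 <- a + b; n2 <- c + d; N <- n1 + n2
  z <- a - n1 * (a + c) / N
  v <- ifelse(N < 2, 0, n1 * n2 * (a + c) * (b + d) / (N^2 * (N - 1)))
  list(z = z, v = v)
}

#' Per-study Peto odds ratio with log-scale standard error
#'
#' The Peto odds ratio is the one-step approximation `exp(Z / V)`, where
#' `Z = a - n1 (a + c) / N` is the observed-minus-expected number of events
#' in the intervention arm and
#' `V = n1 n2 (a + c)(b + d) / (N^2 (N - 1))` is the hypergeometric variance
#' of `a`. The SE of the log Peto odds ratio is `1 / sqrt(V)`.
#'
#' Tables with no events at all (`a + c = 0`) raise a zero-event error;
#' tables with no non-events (`b + d = 0`) or fewer than two patients are
#' degenerate (`V = 0`).
#'
#' @inheritParams relative_risk
#' @return The input as a tibble with added columns `measure` (`"peto_or"`),
#'   `point`, `se_ln` and `provenance` (`"from_counts"`).
#' @examples
#' tibble::tibble(a = 5, b = 5, c = 5, d = 5) |> peto_or()
#' @export
peto_or <- function(data) {
  need_columns(data, c("a", "b", "c", "d"), "`data`")
  a <- data$a; b <- data$b; c <- data$c; d <- data$d
  check_counts(a, b, c, d)
  if (any(a + c == 0)) {
    stop_em("zero_event",
      "No events in either arm: Peto odds ratio is undefined (code Z).",
      code = "Z")
  }
  if (any(b + d == 0) || any(a + b + c + d < 2)) {
    stop_em("degenerate_table",
      "Degenerate table (no non-events, or fewer than two patients): V = 0.")
  }
  zv <- peto_zv(a, b, c, d)
  as_tibble(data) |>
    mutate(measure = "peto_or", point = exp(zv$z / zv$v),
           se_ln = 1 / sqrt(zv$v), provenance = "from_counts")
}

#' Standard error of the log Peto odds ratio
#'
#' `1 / sqrt(V)` with `V` the hypergeometric variance; algebraically equal to
#' `sqrt(N^2 (N - 1) / (n1 n2 (a + c)(b + d)))`.
#'
#' @inheritParams se_ln_rr
#' @return A numeric vector of standard errors.
#' @export
se_ln_peto <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  if (any(a + c == 0)) {
    stop_em("zero_event",
      "No events in either arm: SE of ln(Peto OR) cannot be calculated (code Z).",
      code = "Z")
  }
  if (any(b + d == 0) || any(a + b + c + d < 2)) {
    stop_em("degenerate_table",
      "Degenerate table (no non-events, or fewer than two patients): V = 0.")
  }
  1 / sqrt(peto_zv(a, b, c, d)$v)
}

#' Back-calculate a log-scale standard error from a ratio and its CI
#'
#' Meta-analyses are often reported only as a ratio estimate with a
#' confidence interval. Assuming the interval is a symmetric normal interval
#' on the log scale, the standard error of the log estimate is
#' \deqn{SE = (\ln u - \ln l) / (2 z),}
#' where `z` is the standard-normal quantile at `(1 + confidence) / 2`
#' (1.959964 for 95%).
#'
#' @param point Positive ratio estimate(s).
#' @param lower,upper Positive confidence limits, `lower <= point <= upper`.
#' @param conf_level Coverage of the interval, in (0, 1). Default 0.95.
#' @return A numeric vector of standard errors.
#' @examples
#' se_from_ci(2.39, 1.03, 5.59) # about 0.43
#' @export
se_from_ci <- function(point, lower, upper, conf_level = 0.95) {
  if (any(!is.finite(conf_level)) || any(conf_level <= 0) || any(conf_level >= 1)) {
    stop_em("domain", "`conf_level` must lie strictly between 0 and 1.")
  }
  ok <- is.finite(point) & is.finite(lower) & is.finite(upper) &
    lower > 0 & lower <= point & point <= upper
  if (any(!ok)) {
    stop_em("domain",
      "Confidence limits must satisfy 0 < lower <= point <= upper.")
  }
  z <- qnorm((1 + conf_level) / 2)
  (log(upper) - log(lower)) / (2 * z)
}

#' Absolute risk difference and number needed to treat
#'
#' Computes, for each 2x2 table, the event proportions `p1 = a/n1` (intervention)
#' and `p2 = c/n2` (control), the absolute risk reduction `arr = p2 - p1`, and
#' the number needed to treat `1 / |arr|`. The sign of the effect is carried
#' separately as a benefit/harm direction (for adverse outcomes, fewer events
#' under intervention is benefit). `nnt_display` rounds the NNT up to the next
#' whole patient; `nnt` keeps the exact value.
#'
#' @inheritParams relative_risk
#' @param allow_null If `FALSE` (default), a table with `arr == 0` raises a
#'   null-effect error (the NNT is undefined); if `TRUE`, such rows get
#'   `nnt = NA` and direction `"null"`.
#' @return The input as a tibble with added columns `p1`, `p2`, `arr`, `nnt`,
#'   `nnt_display`, `nnt_direction`.
#' @examples
#' tibble::tibble(a = 10, b = 90, c = 20, d = 80) |> risk_difference_nnt()
#' @export
risk_difference_nnt <- function(data, allow_null = FALSE) {
  need_columns(data, c("a", "b", "c", "d"), "`data`")
  a <- data$a; b <- data$b; c <- data$c; d <- data$d
  check_counts(a, b, c, d)
  p1 <- a / (a + b)
  p2 <- c / (c + d)
  arr <- p2 - p1
  if (any(arr == 0) && !allow_null) {
    stop_em("null_effect",
      "Equal event proportions in both arms: NNT is undefined (arr = 0).")
  }
  nnt <- ifelse(arr == 0, NA_real_, 1 / abs(arr))
  as_tibble(data) |>
    mutate(p1 = p1, p2 = p2, arr = arr, nnt = nnt,
           nnt_display = as.integer(ceiling(nnt)),
           nnt_direction = effect_direction(exp(-sign(arr))))
}

#' Classify a ratio estimate as benefit, harm, or null
#'
#' For adverse-event outcomes (the default) a ratio below 1 means the
#' intervention reduces events, i.e. benefit; above 1, harm. For desirable
#' outcomes set `adverse = FALSE` to invert the mapping. An estimate is null
#' when `|ln(point)|` is below `tol`.
#'
#' @param point Positive ratio estimate(s); `NA` propagates.
#' @param adverse Logical, recycled: is the outcome an adverse event?
#' @param tol Tolerance on `|ln(point)|` for the null call.
#' @return A factor with levels `benefit`, `harm`, `null`.
#' @examples
#' effect_direction(c(0.5, 2.39, 1))
#' @export
effect_direction <- function(point, adverse = TRUE, tol = 1e-12) {
  if (any(!is.na(point) & point <= 0)) {
    stop_em("domain", "`point` must be positive on the ratio scale.")
  }
  lp <- log(point)
  adverse <- rep_len(adverse, length(lp))
  out <- ifelse(is.na(lp), NA_character_,
         ifelse(abs(lp) < tol, "null",
         ifelse(xor(lp < 0, !adverse), "benefit", "harm")))
  factor(out, levels = c("benefit", "harm", "null"))
}
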