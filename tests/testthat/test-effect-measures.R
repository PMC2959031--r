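test_that("relative risk point estimates and log-scale SEs match hand arithmetic", {
  cases <- tibble::tribble(
    ~a, ~b, ~c, ~d, ~point, ~se,
    10, 90, 20, 80, 0.5, NA,
    5, 5, 5, 5, 1.0, NA,
    10, 90, 10, 90, 1.0, sqrt(0.18),
    100, 0, 100, 0, 1.0, 0,
    1, 999, 1, 999, 1.0, sqrt(1 + 1 - 0.001 - 0.001))
  est <- relative_risk(cases[, c("a", "b", "c", "d")])
  expect_equal(est$point, cases$point)
  expect_equal(est$se_ln[!is.na(cases$se)], cases$se[!is.na(cases$se)],
               tolerance = 1e-12)
  expect_equal(round(est$se_ln[3], 5), 0.42426)
  expect_equal(round(est$se_ln[5], 5), 1.41351)
  expect_true(all(est$measure == "rr" & est$provenance == "from_counts"))
})

test_that("zero events raise a classed zero-event error unless corrected", {
  tab <- tibble::tibble(a = 0, b = 100, c = 5, d = 95)
  expect_error(relative_risk(tab), class = "em_zero_event")
  expect_error(se_ln_rr(5, 95, 0, 100), class = "em_zero_event")
  # explicit 0.5 continuity correction is available, off by default
  corrected <- relative_risk(tab, correct_zero = TRUE)
  expect_equal(corrected$point, (0.5 / 101) / (5.5 / 101))
  expect_true(is.finite(corrected$se_ln))
})

test_that("count validation rejects malformed tables", {
  expect_error(se_ln_rr(-1, 5, 5, 5), class = "em_domain")
  expect_error(se_ln_rr(1.5, 5, 5, 5), class = "em_domain")
  expect_error(relative_risk(tibble::tibble(a = 0, b = 0, c = 5, d = 5)),
               class = "em_domain")
})

test_that("Peto odds ratio matches the Z/V definition", {
  est <- peto_or(tibble::tibble(a = 5, b = 5, c = 5, d = 5))
  expect_equal(est$point, 1.0)
  expect_equal(est$se_ln, 1 / sqrt(10000 / 7600), tolerance = 1e-12)
  expect_equal(round(est$se_ln, 5), 0.87178)

  orc <- oracle_peto(10, 90, 10, 90)
  est2 <- peto_or(tibble::tibble(a = 10, b = 90, c = 10, d = 90))
  expect_equal(est2$point, 1.0)
  expect_equal(est2$se_ln, orc$se, tolerance = 1e-12)

  expect_equal(se_ln_peto(1, 1, 1, 1), sqrt(3), tolerance = 1e-12)
  expect_error(peto_or(tibble::tibble(a = 0, b = 5, c = 0, d = 5)),
               class = "em_zero_event")
  expect_error(peto_or(tibble::tibble(a = 5, b = 0, c = 5, d = 0)),
               class = "em_degenerate_table")
})

test_that("the two renderings of the Peto SE agree on random tables", {
  set.seed(42)
  tabs <- random_tables(1000)
  got <- se_ln_peto(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(got, oracle_se_peto_expanded(tabs$a, tabs$b, tabs$c, tabs$d),
               tolerance = 1e-12)
})

test_that("swapping arms negates Z, preserves V, and inverts the Peto OR", {
  set.seed(7)
  tabs <- random_tables(300)
  fwd <- peto_or(tabs)
  rev <- peto_or(dplyr::rename(tabs, a = c, b = d, c = a, d = b))
  expect_equal(rev$point, 1 / fwd$point, tolerance = 1e-9)
  expect_equal(rev$se_ln, fwd$se_ln, tolerance = 1e-12)
  # equal event proportions pin the point at the null
  bal <- peto_or(tibble::tibble(a = 12, b = 28, c = 30, d = 70))
  expect_equal(bal$point, 1.0, tolerance = 1e-12)
})

test_that("SE back-calculation from a confidence interval is exact and scale-invariant", {
  expect_equal(round(se_from_ci(2.39, 1.03, 5.59), 2), 0.43)
  expect_equal(se_from_ci(1, 1, 1), 0)
  expect_equal(se_from_ci(2, 1, 4), log(4) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(round(se_from_ci(2, 1, 4), 5), 0.35365)
  for (k in c(0.01, 0.5, 3, 1000)) {
    expect_equal(se_from_ci(2.39 * k, 1.03 * k, 5.59 * k),
                 se_from_ci(2.39, 1.03, 5.59), tolerance = 1e-12)
  }
  expect_error(se_from_ci(1, 2, 3), class = "em_domain")
  expect_error(se_from_ci(2, 1, 4, conf_level = 1), class = "em_domain")
})

test_that("risk difference and NNT follow the two-proportion arithmetic", {
  rd <- risk_difference_nnt(tibble::tibble(a = c(10, 15), b = c(90, 85),
                                           c = c(20, 20), d = c(80, 80)))
  expect_equal(rd$arr, c(0.10, 0.05))
  expect_equal(rd$nnt_display, c(10L, 20L))
  expect_equal(as.character(rd$nnt_direction), c("benefit", "benefit"))
  # NNT display rounds up to the next whole patient, exact value retained
  rd2 <- risk_difference_nnt(tibble::tibble(a = 10, b = 90, c = 13, d = 87))
  expect_equal(rd2$nnt, 1 / 0.03, tolerance = 1e-12)
  expect_equal(rd2$nnt_display, 34L)
  expect_error(
    risk_difference_nnt(tibble::tibble(a = 10, b = 90, c = 10, d = 90)),
    class = "em_null_effect")
})

test_that("effect direction maps ratios to benefit/harm with adverse override", {
  expect_equal(as.character(effect_direction(c(0.5, 2.39, 1))),
               c("benefit", "harm", "null"))
  expect_equal(as.character(effect_direction(c(0.5, 2), adverse = FALSE)),
               c("harm", "benefit"))
  expect_equal(as.character(effect_direction(1 + 1e-15)), "null")
  expect_error(effect_direction(-1), class = "em_domain")
})

test_that("growing a balanced table never increases either SE", {
  base <- c(a = 6, b = 14, c = 6, d = 14)
  for (m in c(1, 2, 5, 20)) {
    smaller_rr <- se_ln_rr(base["a"] * m, base["b"] * m, base["c"] * m, base["d"] * m)
    smaller_peto <- se_ln_peto(base["a"] * m, base["b"] * m, base["c"] * m, base["d"] * m)
    if (m > 1) {
      expect_lt(smaller_rr, prev_rr)
      expect_lt(smaller_peto, prev_peto)
    }
    prev_rr <- smaller_rr
    prev_peto <- smaller_peto
  }
})

test_that("the log-RR SE radicand is non-negative on random valid tables", {
  set.seed(11)
  tabs <- random_tables(500)
  rad <- 1 / tabs$a + 1 / tabs$c - 1 / (tabs$a + tabs$b) - 1 / (tabs$c + tabs$d)
  expect_true(all(rad >= 0))
  expect_true(all(is.finite(se_ln_rr(tabs$a, tabs$b, tabs$c, tabs$d))))
})
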