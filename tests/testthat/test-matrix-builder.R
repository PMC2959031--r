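ex1 <- load_fixture("example1")
ex2 <- load_fixture("example2")

test_that("step I collects every computable point without omission cutoffs", {
  pts <- build_step1(ex1$records, "all-cause mortality")
  # the level-5 guideline row is code N; everything else is computable,
  # including the very imprecise SE 1.07 trial
  expect_equal(nrow(pts), 9)
  expect_true(any(pts$se_ln > 1))
  expect_equal(sum(pts$se_ln < 0.40), 6)
  expect_true(all(is.finite(pts$se_ln)))
  # sorted by level rank then SE
  expect_true(!is.unsorted(pts$level_rank))
  expect_equal(pts$study_id[1], "Bangalore")

  empty <- build_step1(ex1$records[0, ], "all-cause mortality")
  expect_equal(nrow(empty), 0)
})

test_that("step II places each reporting study in exactly one cell", {
  placed <- build_step2(ex1$records, ex1$specs)
  # Z cells count as reported; N cells are excluded: 40 rows - 11 N codes
  expect_equal(nrow(placed), 29)
  bang <- dplyr::filter(placed, study_id == "Bangalore")
  for (oc in ex1$specs$outcome) {
    lv <- dplyr::filter(bang, outcome == oc)$level
    expect_setequal(as.character(lv), c("1a", "1c"))
  }
  expect_false("AHA Guidelines" %in% placed$study_id)
  # columns are ordered by outcome importance
  expect_equal(levels(placed$outcome),
               c("all-cause mortality", "cardiovascular mortality",
                 "non-fatal myocardial infarction", "non-fatal stroke"))

  single <- tibble::tibble(study_id = "s", level = "1b", outcome = "death",
                           se = 0.2, direction = "harm")
  expect_equal(nrow(build_step2(single)), 1)

  grid <- step2_grid(placed)
  expect_equal(sum(grid[, -1] != ""), dplyr::n_distinct(
    dplyr::select(tibble::as_tibble(placed), level, outcome)))
})

test_that("step III applies both omission rules and partitions by direction", {
  bars <- build_step3(ex1$records, ex1$specs)
  expect_true(all(bars$se_ln < 1.0))
  expect_true(all(bars$level_rank <= 6))
  expect_true(all(bars$height > 0 & bars$height <= 1))
  # the SE 1.07 trial and the SE 1.22/1.11 cells are omitted
  expect_false(any(bars$study_id == "Mangano" &
                     bars$outcome != "all-cause mortality"))
  acm_mavs <- dplyr::filter(bars, study_id == "MaVS",
                            outcome == "all-cause mortality")
  expect_equal(nrow(acm_mavs), 0)
  # benefit panel holds exactly the myocardial-infarction bars
  expect_true(all(bars$outcome[bars$panel == "benefit"] ==
                    "non-fatal myocardial infarction"))
  mi <- dplyr::filter(bars, outcome == "non-fatal myocardial infarction",
                      level == "1a")
  expect_equal(mi$height, 0.90)
  expect_equal(max(dplyr::filter(bars, outcome == "non-fatal myocardial infarction",
                                 level_rank <= 2)$height), 0.90)
  # height decreases strictly with SE within a panel
  for (p in c("benefit", "harm")) {
    sub <- dplyr::arrange(dplyr::filter(tibble::as_tibble(bars), panel == p), se_ln)
    expect_true(all(diff(sub$height) < 0 | diff(sub$se_ln) == 0))
  }
})

test_that("the example-2 benefit panel is empty", {
  bars <- build_step3(ex2$records, ex2$specs)
  expect_equal(sum(bars$panel == "benefit"), 0)
  expect_setequal(dplyr::filter(bars, panel == "harm")$study_id,
                  c("PAFAC", "Sodermark", "Lafuente-Lafuente"))
})

test_that("step III cutoffs are honoured and validated", {
  strict <- build_step3(ex1$records, ex1$specs, se_cutoff = 0.3,
                        level_cutoff = "1b")
  expect_true(all(strict$se_ln < 0.3))
  expect_true(all(strict$level_rank <= 2))
  expect_error(build_step3(ex1$records, ex1$specs, se_cutoff = 0),
               class = "em_domain")
  expect_error(build_step3(ex1$records, ex1$specs, level_cutoff = "9z"),
               class = "em_unknown_level")
})

test_that("null-direction estimates land in neither panel, with a message", {
  recs <- tibble::tibble(
    study_id = c("null_trial", "harm_trial"), level = "1b", outcome = "death",
    a = c(10, 20), b = c(90, 80), c = c(10, 10), d = c(90, 90))
  expect_message(bars <- build_step3(recs), "neither panel")
  expect_equal(nrow(bars), 1)
  expect_equal(bars$study_id, "harm_trial")
  expect_equal(as.character(bars$panel), "harm")
})

test_that("step III serialization is deterministic and faithful", {
  bars <- build_step3(ex1$records, ex1$specs)
  j1 <- jsonlite::toJSON(serialize_step3(bars), auto_unbox = TRUE, digits = NA)
  j2 <- jsonlite::toJSON(serialize_step3(build_step3(ex1$records, ex1$specs)),
                         auto_unbox = TRUE, digits = NA)
  expect_identical(as.character(j1), as.character(j2))
  parsed <- jsonlite::fromJSON(j1)
  expect_equal(parsed$se_cutoff, 1.0)
  expect_equal(sort(names(parsed$panels)), c("benefit", "harm"))
  n_bars <- sum(vapply(parsed$panels, function(p) sum(vapply(p, nrow, 1L)), 1L))
  expect_equal(n_bars, nrow(bars))
})

test_that("step IV screens outcomes on both error dimensions", {
  # example 2: the best available evidence has a high risk of random error,
  # so the effect size must not be summarised
  s4 <- build_step4(ex2$records, ex2$specs)
  expect_equal(s4$status, "insufficient_evidence")
  expect_match(s4$reasons, "random error")
  expect_true(is.na(s4$nnt))

  # a synthetic trial with counts that passes the screen yields the NNT
  recs <- tibble::tibble(study_id = "trial", level = "1b", outcome = "death",
                         a = 10, b = 90, c = 20, d = 80)
  s4b <- build_step4(recs, max_band = "substantial")
  expect_equal(s4b$status, "ok")
  expect_equal(s4b$nnt_display, 10L)
  expect_equal(s4b$direction, "benefit")
  expect_equal(s4b$arr, 0.1)

  # when nothing passes, every outcome is reported as insufficient
  s4c <- build_step4(recs, max_band = "ignorable")
  expect_equal(s4c$status, "insufficient_evidence")
  expect_match(s4c$reasons, "random error")
  no_ev <- tibble::tibble(study_id = "g", level = "5", outcome = "death",
                          code = "N")
  s4d <- build_step4(no_ev)
  expect_equal(s4d$status, "insufficient_evidence")
  expect_match(s4d$reasons, "no computable evidence")
  expect_error(build_step4(recs, max_band = "galactic"), class = "em_domain")
})

test_that("step IV reports the best available estimate without counts as direction only", {
  s4 <- build_step4(ex1$records, ex1$specs, max_band = "moderate")
  expect_equal(s4$outcome, order_outcomes(ex1$specs)$outcome)
  expect_equal(s4$status, rep("ok", 4))
  expect_equal(s4$study_id, rep("Bangalore", 4))
  expect_equal(s4$level, rep("1a", 4))
  expect_equal(s4$direction, c("harm", "harm", "benefit", "harm"))
  expect_true(all(is.na(s4$nnt)))  # reported SEs carry no 2x2 counts
})
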