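---
title: "Methods behind the error matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the error matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errormatrix)
library(dplyr)
```

## The three error dimensions

The error matrix summarises a body of clinical intervention evidence along
three dimensions that jointly determine how far a reported effect can be
trusted.

**Systematic error (bias)** is captured as an ordinal levels-of-evidence
label, 1a through 5, with rank 1 the most trustworthy design
(meta-analysis of randomized trials with low risk of bias) and rank 10 the
least (expert opinion). The package treats the level as a user-supplied
judgment: appraising allocation concealment, blinding and the other bias
components is expert work, not computation, so `parse_level()` validates
and orders labels but never assigns them.

**Random error (play of chance)** is quantified as the standard error of
the natural log of a ratio effect measure. Unlike a p-value, which varies
with both effect size and accumulation of data, the SE is a pure
uncertainty measure and is comparable across studies of different sizes.
Three routes produce it:

* from 2x2 counts, as `SE[ln RR]` or `SE[ln OR_Peto]`
  (`relative_risk()`, `peto_or()`);
* from fixed-effect pooling over a trial set (`mh_pooled_rr()`,
  `peto_pooled_or()`);
* back-calculated from a reported estimate and confidence interval
  (`se_from_ci()`), assuming a symmetric normal interval on the log scale.

All logs are natural logs. Base-10 would rescale every SE by the same
constant and leave all orderings and band boundaries' interpretation
intact only if the bands were rescaled too, so a single convention is
used throughout.

**Design error (external validity)** is expressed through outcome
importance: a 1-9 grade from the patient's perspective (9 = mortality),
with 7-9 critical, 4-6 important but not critical, and 1-3 not important.
Outcomes in different categories are never interchangeable, which is why
`order_outcomes()` sorts strictly by descending grade before any
tie-breaking.

## Risk bands and their boundaries

`classify_random_error()` bins SEs into ignorable `[0, 0.10)`, small
`[0.10, 0.20)`, moderate `[0.20, 0.30)`, substantial `[0.30, 0.50)` and
high `[0.50, Inf)`. The published band descriptions state overlapping
endpoints ("0.10 to 0.20", "0.20 to 0.30"); since an SE of exactly 0.10 is
described as a *small* risk, the package resolves the ambiguity as
left-closed/right-open intervals with every boundary belonging to the
upper band. The classifier is total and monotone on `[0, Inf)` and the
bands can be overridden through the YAML config (`read_matrix_config()`)
as long as they still partition the half-line.

## The four steps

* **Step I** (`build_step1()`): per outcome, one point per study with a
  computable SE, on (SE, level-rank) axes. Deliberately no cutoffs: a
  trial with SE above 1 is still information about how weak the evidence
  is.
* **Step II** (`build_step2()`): each study placed in its
  (level, outcome) cell for every outcome it reports. Zero-event outcomes
  (code Z) count as reported; not-reported outcomes (code N) do not.
* **Step III** (`build_step3()`): the Manhattan landscape. The published
  figure defines no numeric bar height, so the package uses the linear
  transform `height = (c - min(SE, c)) / c` with SE cutoff `c` (default
  1.0). Linearity keeps the height strictly monotone in SE, and makes the
  omission threshold and zero height coincide, so "omitted because SE >=
  cutoff" and "bar of height zero" are the same rule. Bars at levels worse
  than the level cutoff (default 2b) are omitted, matching the published
  figures. Each bar is assigned to the benefit or the harm panel by the
  direction of its own estimate; estimates exactly at the null
  (`|ln point| < 1e-12`) belong to neither panel and are dropped with a
  message rather than silently or arbitrarily assigned.
* **Step IV** (`build_step4()`): effect size last. An outcome is
  summarised (best-available estimate, direction, absolute risk reduction
  and NNT when counts exist) only if its best evidence passes a screen on
  both internal-validity dimensions — by default level at or better than
  2b and band at or better than moderate. Anything else is reported as
  `insufficient_evidence` with the failing dimension(s) named, because
  reading an effect size off invalid evidence is exactly the mistake the
  matrix is built to prevent.

## Estimators and conventions

* **Peto odds ratio.** `exp(Z/V)` with `Z = a - n1(a+c)/N` and the
  hypergeometric variance `V`. The SE `1/sqrt(V)` is algebraically
  identical to the count-expanded form
  `sqrt(N^2(N-1)/(n1 n2 (a+c)(b+d)))`; the equality is property-tested to
  1e-12 over random tables. Computation coerces counts to double first:
  the `V` numerator overflows 32-bit integers already for trials with a
  few hundred patients per arm.
* **Mantel-Haenszel pooling.** The SE uses the P/R/S component sums; the
  point estimate `R/S` is the conventional MH estimator consistent with
  those symbols, and is needed to assign a pooled result to a panel. For a
  single stratum the MH SE collapses exactly to the per-study `SE[ln RR]`
  (verified over 1000 random tables). Fixed-effect only; heterogeneity
  assessment is deliberately outside the matrix.
* **Zero events.** No continuity correction by default: a table with zero
  events in a required margin cannot yield an SE, and is recorded as code
  Z instead of being nudged with pseudo-counts. An explicit
  `correct_zero = TRUE` flag adds 0.5 to all four cells for users who want
  the conventional correction; it never switches on silently. In pooling,
  trials with zero total events contribute zero to every component sum
  and are dropped with a warning rather than aborting the pool.
* **CI back-calculation.** Uses `z = qnorm(0.975) = 1.959964`, not the
  rounded 1.96, to avoid a small systematic bias; displayed SEs are
  rounded to two decimals only at the reporting edge.
* **NNT.** `1/|arr|` kept exact internally; the display value rounds up
  to the next whole patient, and the sign is carried separately as a
  benefit/harm direction.
* **Direction convention.** All default outcomes are adverse events, so a
  ratio below 1 is benefit. A per-outcome `adverse = FALSE` flag in the
  outcome specification inverts the mapping for desirable outcomes.
* **Best available evidence.** Level first, then SE, then study id — a
  strict lexicographic rule. The level-first choice means a very imprecise
  1b trial outranks a precise 1c meta-analysis; that matches the
  hierarchy's logic (bias cannot be averaged away by precision) and is
  deterministic under ties, which the published tables never exhibit but
  tests require. Per-level queries ("best 1b study") are expressed by
  filtering the records before the call.

## Packaged fixtures

The two worked examples ship as plain CSV study tables. The published
tables print per-study SEs but not the underlying 2x2 counts, so the
fixtures carry the SEs as reported (`provenance = "as_reported"`) together
with benefit/harm direction flags taken from the published conclusions;
provenance is surfaced in every output so these can never be mistaken for
values the package computed. The one row reported as an odds ratio with a
95% CI is back-calculated on load and reproduces the printed SE 0.43. The
correctness of the SE formulas themselves rests on the hand-computed
oracles and property suites, not on these fixtures.

## The synthetic trial generator

`generate_synthetic_trials()` emulates a modest meta-analysis:
parallel-group trials, per-arm sizes uniform on 50-500, control event
probability 0.2, true relative risk 0.8, binomial event counts. Those
defaults give per-trial SEs spanning roughly the small to high bands,
which is the regime the matrix is designed to discriminate. What it does
not emulate: between-trial heterogeneity in the true effect, correlated
outcomes, non-inferiority designs, informative missingness, or
publication bias — so green property tests show the estimators and the
matrix assembly are arithmetically and structurally correct, not that the
approach is robust to those real-data features. Seeded runs are exactly
reproducible and restore the caller's RNG state.

Problem sizes used by the test and acceptance runs — 1000 random tables
for the algebraic identities, 500-1000 seeded replicates of five trials
of 200-400 patients per arm for the null-calibration check — were chosen
to make the identity checks overwhelming (they hold to 1e-12) and the
calibration estimate stable to within about one percentage point.

## Known limitations

* The matrix is a relative overview, not an absolute measure: positions
  of studies are comparable within one question, not across questions.
* SEs ignore multiplicity (repeated looks, many outcomes) and
  correlations between outcomes (cardiovascular mortality is contained in
  all-cause mortality); each outcome is treated marginally.
* Evidence levels are inputs; the package cannot detect a mislabelled
  study.
* Bar height is a display transform, not a statistic: differences in
  height between two bars carry no inferential meaning.
* The Bayes factor as an alternative ranking device and sequential
  monitoring adjustments are out of scope.
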