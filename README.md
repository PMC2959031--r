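# errormatrix

Clinical intervention evidence keeps growing, and a stack of trials,
meta-analyses and guidelines of very different quality is hard to overview.
`errormatrix` implements a four-step "error matrix" that ranks a body of
evidence along three error dimensions and shows it at a glance:

* **systematic error** (bias) — an ordinal levels-of-evidence scale from 1a
  (meta-analysis of randomized trials with low risk of bias) to 5 (expert
  opinion);
* **random error** (play of chance) — quantified, comparably across studies
  of any size, as the standard error of the log effect measure, and
  classified into five named risk bands;
* **design error** (external validity) — outcome importance graded 1–9 from
  the patient's perspective (9 = mortality; 7–9 critical, 4–6 important,
  1–3 not important).

The package is aimed at systematic reviewers, guideline developers and
methodologists who need to judge whether the available evidence on an
intervention is internally and externally valid before reading anything
into its effect size.

## The statistics at the core

For a two-arm study with `a`/`b` events/non-events among `n1` intervention
patients and `c`/`d` among `n2` controls (`N = n1 + n2`):

* relative risk `RR = (a/n1) / (c/n2)`, with
  `SE[ln RR] = sqrt(1/a + 1/c − 1/n1 − 1/n2)`;
* Peto odds ratio `OR = exp(Z/V)`, where `Z = a − n1(a+c)/N` and
  `V = n1·n2·(a+c)·(b+d) / (N²(N−1))`, with `SE[ln OR] = 1/sqrt(V)`;
* Mantel–Haenszel fixed-effect pooling across trials: point estimate `R/S`
  and `SE[ln RR_MH] = sqrt(P/(R·S))` with
  `P = Σ (n1·n2·(a+c) − a·c·N)/N²`, `R = Σ a·n2/N`, `S = Σ c·n1/N`;
* pooled Peto odds ratio `exp(ΣZ/ΣV)` with `SE = 1/sqrt(ΣV)`;
* for results reported only as an estimate with a 95% CI,
  `SE = (ln upper − ln lower) / (2 × 1.959964)`.

Standard errors are then binned into risk-of-random-error bands:
ignorable `[0, 0.10)`, small `[0.10, 0.20)`, moderate `[0.20, 0.30)`,
substantial `[0.30, 0.50)`, high `[0.50, ∞)`.

The four matrix steps are `build_step1()` (level-by-SE scatter per
outcome), `build_step2()` (study placements in the outcome-importance ×
evidence-level grid), `build_step3()` (the two-panel benefit/harm
"Manhattan" bar landscape, where bar height `(1 − SE)/1` makes the best
evidence the tallest skyscrapers on the upper west side), and
`build_step4()` (effect size and direction — e.g. the number needed to
treat — computed only for outcomes whose best evidence passes a validity
screen on both error dimensions).

## Worked example

The packaged `example2` fixture holds the evidence on class 1a
antiarrhythmics for maintaining sinus rhythm after cardioversion of atrial
fibrillation (outcome: all-cause mortality). The meta-analysis row is
reported as OR 2.39 (95% CI 1.03–5.59); its SE is back-calculated on load.

```r
library(errormatrix)
library(dplyr)

ex2 <- load_fixture("example2")
compute_estimates(ex2$records, specs = ex2$specs) |>
  select(study_id, level, se_ln, provenance, band, direction)
#> # A tibble: 9 × 6
#>   study_id          level  se_ln provenance  band        direction
#> 1 Byrne-Quinn       1d     2.02  as_reported high        harm
#> 2 Hillestad         1d     2     as_reported high        harm
#> 3 Karlson           1d     1.42  as_reported high        harm
#> 4 Lloyd             1d     1.55  as_reported high        harm
#> 5 PAFAC             1b     0.78  as_reported high        harm
#> 6 Sodermark         1d     0.73  as_reported high        harm
#> 7 SOPAT             1b     1.51  as_reported high        harm
#> 8 Steinbeck         1d    NA     <NA>        <NA>        <NA>
#> 9 Lafuente-Lafuente 1c     0.431 from_ci     substantial harm
```

Every computable SE is at least 0.43, i.e. substantial-to-high risk of
random error, and the best randomized trial with low risk of bias sits at
SE 0.78:

```r
best_available(ex2$records, "all-cause mortality") |>
  select(study_id, level, se_ln, band)
#> # A tibble: 1 × 4
#>   study_id level se_ln band
#> 1 PAFAC    1b     0.78 high
```

Step IV therefore refuses to summarise an effect size — the direction
(harm) is only as reliable as the errors behind it:

```r
build_step4(ex2$records, ex2$specs) |>
  select(outcome, status, reasons, study_id, se_ln, band)
#> # A tibble: 1 × 6
#>   outcome             status                reasons      study_id se_ln band
#> 1 all-cause mortality insufficient_evidence random error PAFAC     0.78 high
```

`build_step3()` plus `autoplot()` or `render_manhattan()` draw the
two-panel Manhattan figure for this fixture with an empty benefit panel —
the "upper west side" is empty at a glance.

Pooling works on plain tables of counts, with broom-style accessors:

```r
trials <- generate_synthetic_trials(n_trials = 4, seed = 42)
tidy(mh_pooled_rr(trials))
#> # A tibble: 1 × 6
#>   measure estimate log_estimate std_error_log band  direction
#> 1 rr_mh      0.956      -0.0450         0.105 small benefit
```

A small CLI covers the same ground from a shell (see `?em_cli`), e.g.
`error-matrix step1 --fixture example1 --outcome "all-cause mortality"
--max-se 0.40 --count` prints `6`.

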