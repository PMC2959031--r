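#' Generate a synthetic set of two-arm trials
#'
#' Draws `n_trials` parallel-group trials with per-arm sample sizes uniform
#' on `n_range`, control-arm event probability `p_control`, and intervention
#' event probability `p_control * true_rr` (clamped to stay inside (0, 1)).
#' Event counts are binomial. All randomness flows through R's generator:
#' with `seed` set the output is fully reproducible and the caller's RNG
#' state is left untouched.
#'
#' The defaults (10 trials of 50-500 patients per arm, 20% control event
#' risk, true relative risk 0.8) emulate a modest meta-analysis of common
#' adverse outcomes; they give per-trial SEs spanning roughly the small to
#' high risk-of-random-error bands.
#'
#' @param n_trials Number of trials (>= 1).
#' @param n_range Length-2 integer range of per-arm sample sizes.
#' @param p_control Control-arm event probability, strictly in (0, 1).
#' @param true_rr True relative risk (> 0).
#' @param seed Optional integer seed.
#' @return A tibble with columns `study_id`, `a`, `b`, `c`, `d`.
#' @examples
#' generate_synthetic_trials(n_trials = 3, seed = 1)
#' @export
generate_synthetic_trials <- function(n_trials = 10, n_range = c(50, 500),
                                      p_control = 0.2, true_rr = 0.8,
                                      seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1 ||
      n_trials != trunc(n_trials)) {
    stop_em("config", "`n_trials` must be a whole number >= 1.")
  }
  if (!is.numeric(n_range) || length(n_range) != 2 || any(n_range < 2) ||
      n_range[1] > n_range[2]) {
    stop_em("config", "`n_range` must be an increasing range of sizes >= 2.")
  }
  if (!is.numeric(p_control) || length(p_control) != 1 ||
      p_control <= 0 || p_control >= 1) {
    stop_em("config", "`p_control` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(true_rr) || length(true_rr) != 1 || true_rr <= 0) {
    stop_em("config", "`true_rr` must be positive.")
  }
  p_int <- min(max(p_control * true_rr, 1e-6), 1 - 1e-6)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  n1 <- sample(seq(n_range[1], n_range[2]), n_trials, replace = TRUE)
  n2 <- sample(seq(n_range[1], n_range[2]), n_trials, replace = TRUE)
  a <- rbinom(n_trials, n1, p_int)
  c <- rbinom(n_trials, n2, p_control)
  tibble(study_id = sprintf("trial%02d", seq_len(n_trials)),
         a = a, b = n1 - a, c = c, d = n2 - c)
}
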