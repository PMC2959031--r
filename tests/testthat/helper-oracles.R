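# Independent arithmetic oracles, written directly from the defining
# formulas; they never call the package's own implementations.

oracle_se_rr <- function(a, b, c, d) {
  sqrt(1 / a + 1 / c - 1 / (a + b) - 1 / (c + d))
}

oracle_peto <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; N <- n1 + n2
  z <- a - n1 * (a + c) / N
  v <- n1 * n2 * (a + c) * (b + d) / (N^2 * (N - 1))
  list(z = z, v = v, point = exp(z / v), se = 1 / sqrt(v))
}

# count-expanded rendering of the Peto SE
oracle_se_peto_expanded <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; N <- n1 + n2
  sqrt(N^2 * (N - 1) / (n1 * n2 * (a + c) * (b + d)))
}

oracle_mh <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; N <- n1 + n2
  P <- sum((n1 * n2 * (a + c) - a * c * N) / N^2)
  R <- sum(a * n2 / N)
  S <- sum(c * n1 / N)
  list(point = R / S, se = sqrt(P / (R * S)))
}

# random valid tables with events and non-events in both margins
# (double-typed so the plain-arithmetic oracles cannot overflow integers)
random_tables <- function(n, max_n = 200) {
  n1 <- sample(3:max_n, n, replace = TRUE)
  n2 <- sample(3:max_n, n, replace = TRUE)
  a <- vapply(n1, function(k) sample(seq_len(k - 1), 1), integer(1))
  c <- vapply(n2, function(k) sample(seq_len(k - 1), 1), integer(1))
  tibble::tibble(a = as.numeric(a), b = as.numeric(n1 - a),
                 c = as.numeric(c), d = as.numeric(n2 - c))
}
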