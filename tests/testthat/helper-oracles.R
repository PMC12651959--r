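# Independent brute-force oracles, written as plain loops so they share no
# code path with the implementation they check.

oracle_percent <- function(v) {
  tot <- 0
  for (x in v) tot <- tot + x
  out <- numeric(length(v))
  for (i in seq_along(v)) out[i] <- 100 * v[i] / tot
  out
}

oracle_fw <- function(fractions, percent) {
  s <- 0
  for (i in seq_along(fractions)) s <- s + fractions[i] * percent[i]
  s / 100
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

oracle_t_paired <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - m)^2
  m / (sqrt(ss / (n - 1)) / sqrt(n))
}

# one qPCR profile as a tidy Cq tibble
cq_profile <- function(cq, gene = "G", sample_id = "s1", treatment = "DMEM",
                       replicate = 1L, fraction = seq_along(cq)) {
  tibble::tibble(
    sample_id = sample_id, treatment = treatment, replicate = replicate,
    fraction = as.integer(fraction), gene = gene, cq = cq
  )
}

# weighted mean fraction of a raw weight vector over a window (for checking
# apply_shift without going through the percent pipeline)
oracle_window_fw <- function(w, window) {
  idx <- window[1]:window[2]
  num <- den <- 0
  for (i in idx) {
    num <- num + i * w[i]
    den <- den + w[i]
  }
  num / den
}
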