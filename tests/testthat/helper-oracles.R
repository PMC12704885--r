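# Independent oracles: literal formula evaluations and brute-force
# enumerations, kept free of any package internals.

oracle_shannon <- function(p) {
  s <- 0
  for (x in p) s <- s - x * log(x) / log(2)
  s
}

oracle_renyi <- function(p, alpha) {
  if (alpha == 0) return(log(length(p)) / log(2))
  s <- 0
  for (x in p) s <- s + x^alpha
  (1 / (1 - alpha)) * log(s) / log(2)
}

oracle_min_entropy <- function(p) {
  -log(max(p)) / log(2)
}

# Random frequency table drawn from the ambient RNG state.
random_freq_table <- function(max_vocab = 1000) {
  v <- sample(2:max_vocab, 1)
  counts <- sample(1:50, v, replace = TRUE)
  build_frequency_table(rep(paste0("t", seq_len(v)), counts))
}

# Exact two-sided signed-rank p-value by full 2^n enumeration of sign
# assignments (zeros discarded, midranks), doubled smaller tail of W+.
enumerate_signed_rank_p <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- as.vector(signs %*% r)
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Brute-force AUC by pair counting.
brute_auc <- function(minor, guardian) {
  tot <- 0
  for (m in minor) {
    for (g in guardian) {
      tot <- tot + (g > m) + 0.5 * (g == m)
    }
  }
  tot / (length(minor) * length(guardian))
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (no ties assumed), using the doubled-tail convention wilcox.test uses.
enumerate_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Small deterministic paired corpus for integration tests.
tiny_paired_corpus <- function(n_pairs = 4, seed = 101,
                               minor_v = 60, guardian_v = 120,
                               minor_len = 300, guardian_len = 900,
                               sections = FALSE) {
  generate_paired_corpus(
    paired_corpus_spec(
      n_pairs = n_pairs,
      minor_params = zipf_params(minor_v, 1.05, 2),
      guardian_params = zipf_params(guardian_v, 1.05, 2),
      minor_length = minor_len,
      guardian_length = guardian_len,
      sections = sections
    ),
    seed = seed
  )
}
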