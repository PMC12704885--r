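make_spectra <- function(values) {
  # values: named list pair_id -> list(minor = h vector, guardian = h vector)
  # over a common alpha grid inferred from the vector length
  rows <- list()
  for (pid in names(values)) {
    for (grp in c("minor", "guardian")) {
      h <- values[[pid]][[grp]]
      grid <- seq(0, by = 0.5, length.out = length(h))
      rows[[paste(pid, grp)]] <- tibble::tibble(
        doc_id = paste0(pid, "_", grp), group = grp, pair_id = pid,
        n_tokens = 100L, alpha = grid, entropy_bits = h,
        estimator = "renyi"
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("entropy_spectra", class(out))
  out
}

test_that("paired_deltas pairs spectra and subtracts minor from guardian", {
  sp <- make_spectra(list(p1 = list(minor = c(2, 2), guardian = c(3, 3))))
  d <- paired_deltas(sp)
  expect_equal(d$delta, c(1, 1))
  expect_equal(d$h_guardian, c(3, 3))

  same <- make_spectra(list(p1 = list(minor = c(2, 1), guardian = c(2, 1))))
  expect_equal(paired_deltas(same)$delta, c(0, 0))

  corpus <- tiny_paired_corpus(n_pairs = 3)
  sp17 <- entropy_spectra(corpus, grid = default_alpha_grid())
  expect_equal(nrow(paired_deltas(sp17)), 3 * 21)
})

test_that("paired_deltas rejects incomplete pairs and mismatched grids", {
  sp <- make_spectra(list(p1 = list(minor = c(2, 2), guardian = c(3, 3))))
  expect_error(paired_deltas(sp[sp$group == "minor", ]), "incomplete")

  mism <- sp
  mism$alpha[mism$group == "guardian"] <- c(0, 0.7)
  expect_error(paired_deltas(mism), "mismatched")
})

test_that("signed_rank_test matches its worked small-sample cases", {
  res <- signed_rank_test(c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$method, "exact")
  expect_equal(res$w_statistic, 15)
  expect_equal(res$n_positive, 5L)

  tied <- signed_rank_test(c(1, -1))
  expect_equal(tied$p_value, 1)

  big <- signed_rank_test(seq_len(30))
  expect_equal(big$method, "normal_approx")

  withz <- signed_rank_test(c(0, 0, 1, -2, 3))
  expect_equal(withz$n_zero, 2L)
  expect_equal(withz$n_used, 3L)

  expect_error(signed_rank_test(c(0, 0)), "no nonzero")
})

test_that("exact signed-rank p-values equal full sign-assignment enumeration", {
  withr::with_seed(21, {
    for (i in 1:25) {
      n <- sample(2:10, 1)
      d <- sample(c(-3:3), n, replace = TRUE)
      if (all(d == 0)) d[1] <- 1
      expect_equal(signed_rank_test(d)$p_value, enumerate_signed_rank_p(d),
                   info = paste(d, collapse = ","))
    }
  })
})

test_that("normal approximation is close to the exact tail at moderate n", {
  withr::with_seed(22, {
    d <- rnorm(24, mean = 0.4)
    p_exact <- signed_rank_test(d)$p_value
    p_approx <- signed_rank_test(d, exact_limit = 10)$p_value
    expect_equal(signed_rank_test(d, exact_limit = 10)$method, "normal_approx")
    expect_lt(abs(p_exact - p_approx), 0.01)
  })
})

test_that("rank_auc counts concordant pairs with ties at half weight", {
  expect_equal(rank_auc(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(rank_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(rank_auc(c(1, 2, 5), c(3, 4, 5)), 6.5 / 9)
})

test_that("rank_auc equals brute-force counting and obeys its symmetries", {
  withr::with_seed(23, {
    for (i in 1:30) {
      m <- sample(1:10, sample(2:12, 1), replace = TRUE)
      g <- sample(1:10, sample(2:12, 1), replace = TRUE)
      a <- rank_auc(m, g)
      expect_equal(a, brute_auc(m, g))
      expect_equal(rank_auc(g, m), 1 - a)
      expect_equal(rank_auc(exp(m), exp(g)), a) # monotone-transform invariance
    }
  })
})

test_that("youden_threshold maximises J over midpoint cutoffs, lowest on ties", {
  sep <- youden_threshold(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$threshold, 3.5)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$auc, 1)

  degen <- youden_threshold(c(1, 2, 3), c(1, 2, 3))
  expect_equal(degen$youden_j, 0)
  expect_equal(degen$sensitivity + degen$specificity, 1)

  # brute-force scan over candidate cutoffs is the defining oracle
  m <- c(1, 2, 5); g <- c(3, 4, 5)
  got <- youden_threshold(m, g)
  v <- sort(unique(c(m, g)))
  cand <- c(-Inf, (head(v, -1) + tail(v, -1)) / 2, Inf)
  j <- vapply(cand, function(t) mean(g >= t) + mean(m < t) - 1, numeric(1))
  expect_equal(got$youden_j, max(j))
  expect_equal(got$threshold, cand[which.max(j)])
})

test_that("paired_test_table reports one signed-rank row per alpha", {
  corpus <- tiny_paired_corpus(n_pairs = 6)
  sp <- entropy_spectra(corpus, grid = report_alphas())
  tab <- paired_test_table(paired_deltas(sp))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$n_positive + tab$n_negative + tab$n_zero, rep(6L, 4))
  # richer guardian vocabulary dominates at alpha = 0
  expect_equal(tab$n_positive[tab$alpha == 0], 6L)
})

test_that("roc_table separates groups per alpha", {
  corpus <- tiny_paired_corpus(n_pairs = 6)
  sp <- entropy_spectra(corpus, grid = report_alphas())
  roc <- roc_table(sp)
  expect_equal(nrow(roc), 4L)
  expect_true(all(roc$auc >= 0 & roc$auc <= 1))
  expect_equal(roc$auc[roc$alpha == 0], 1) # disjoint vocabulary sizes
})

test_that("spearman_rho matches the rank formula and rejects degenerate input", {
  expect_equal(spearman_rho(1:5, 2:6)$rho, 1)
  expect_equal(spearman_rho(1:5, 6:2)$rho, -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})
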