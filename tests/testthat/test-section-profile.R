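sectioned_pair <- function(minor_tokens, guardian_tokens, sections_m,
                           sections_g) {
  tibble::tibble(
    doc_id = c("m", "g"),
    group = c("minor", "guardian"),
    pair_id = "p1",
    n_tokens = c(length(minor_tokens), length(guardian_tokens)),
    tokens = list(minor_tokens, guardian_tokens),
    sections = list(sections_m, sections_g)
  )
}

test_that("identical section texts give zero differences everywhere", {
  toks <- rep(c("a", "b", "c", "d"), 10)
  sec <- tibble::tibble(section = c("introduction", "procedures"),
                        start = c(1L, 21L), end = c(20L, 40L))
  corpus <- sectioned_pair(toks, toks, sec, sec)
  tab <- section_delta_table(corpus, alphas = report_alphas())
  expect_equal(nrow(tab), 2 * 4)
  expect_equal(tab$mean_delta, rep(0, 8))
})

test_that("richer guardian sections give positive deltas shrinking with alpha", {
  corpus <- tiny_paired_corpus(n_pairs = 6, sections = TRUE,
                               minor_len = 400, guardian_len = 1600)
  tab <- section_delta_table(corpus, alphas = c(0, 1.5))
  expect_equal(nrow(tab), 4 * 2)
  wide <- tidyr::pivot_wider(tab[, c("section", "alpha", "mean_delta")],
                             names_from = "alpha", values_from = "mean_delta")
  expect_true(all(wide$`0` > wide$`1.5`))
  expect_true(all(wide$`1.5` > 0))
})

test_that("a section present in one member only is an error naming it", {
  toks <- rep(letters[1:5], 8)
  sec_m <- tibble::tibble(section = "introduction", start = 1L, end = 20L)
  sec_g <- tibble::tibble(section = "procedures", start = 1L, end = 20L)
  corpus <- sectioned_pair(toks, toks, sec_m, sec_g)
  expect_error(section_delta_table(corpus), "p1/introduction")
})

test_that("section spectra obey the alpha-monotonicity invariant", {
  corpus <- tiny_paired_corpus(n_pairs = 2, sections = TRUE)
  sp <- section_spectra(corpus, grid = default_alpha_grid())
  for (key in split(seq_len(nrow(sp)), paste(sp$doc_id, sp$section))) {
    vals <- sp$entropy_bits[key][order(sp$alpha[key])]
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("tt_density applies the occurrence-over-total formula", {
  expect_equal(tt_density(c("化疗", "方案", "知情"), "化疗"), 1 / 3)
  expect_equal(tt_density(c("a", "b"), "z"), 0)
  expect_equal(tt_density(c("a", "b"), c("a", "b")), 1)
  expect_warning(res <- tt_density(c("a", "b"), character(0)), "empty lexicon")
  expect_equal(res, 0)
})

test_that("multi-token terms match greedily and count their full length", {
  toks <- c("acute", "renal", "failure", "risk")
  # the 3-token term wins over the shorter prefix term
  expect_equal(tt_density(toks, c("acute renal", "acute renal failure")), 3 / 4)
  expect_equal(tt_density(toks, "renal failure"), 2 / 4)
  # matches cannot overlap: the second term starts after the first match
  expect_equal(tt_density(c("a", "b", "c"), c("a b", "b c")), 2 / 3)
})

test_that("tt_density is order-invariant for single-token lexica and mixes by length", {
  withr::with_seed(41, {
    toks <- sample(c(paste0("w", 1:20), "term1", "term2"), 200, replace = TRUE)
  })
  lex <- c("term1", "term2")
  expect_equal(tt_density(toks, lex), tt_density(rev(toks), lex))

  a <- rep(c("term1", "x"), 10)   # density 1/2
  b <- rep("y", 30)               # density 0
  expect_equal(tt_density(c(a, b), lex),
               (length(a) * tt_density(a, lex) + length(b) * 0) /
                 (length(a) + length(b)))
})

test_that("tt_entropy_correlation recovers a constructed monotone relationship", {
  lex <- paste0("tt", 1:10)
  base <- zipf_params(100, 1.1, 2)
  rates <- seq(0, 0.27, by = 0.03)
  docs <- purrr::imap(rates, function(r, i) {
    toks <- sample_document(base, 2000, seed = 50, doc_id = paste0("d", i))
    inject_terms(toks, lex, r, seed = 50, doc_id = paste0("d", i))
  })
  corpus <- tibble::tibble(
    doc_id = paste0("d", seq_along(docs)), group = "other",
    pair_id = NA_character_, n_tokens = lengths(docs), tokens = docs,
    sections = vector("list", length(docs))
  )
  res <- tt_entropy_correlation(corpus, lex, alpha = 1.5)
  expect_gt(res$rho, 0)
  per_doc <- attr(res, "by_document")
  expect_equal(nrow(per_doc), length(rates))
  expect_true(all(abs(per_doc$tt - rates) < 0.03))

  const <- corpus
  const$tokens <- purrr::map(const$tokens, function(x) rep(c("a", "b"), 50))
  expect_error(tt_entropy_correlation(const, lex), "undefined correlation")
  expect_error(tt_entropy_correlation(corpus[1:2, ], lex), "at least 3")
})
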