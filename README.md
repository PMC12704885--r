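# entroread

Entropy-based lexical readability analysis for paired document corpora,
built for the comparison of simplified and full versions of Chinese
informed-consent forms (ICFs) — the version written for minor study
participants against the version written for their guardians — and for
benchmarking such documents against grade-level reference corpora.

## Why entropy

Readability formulas built on syllable counts do not transfer to Chinese.
A signal that does transfer is lexical complexity: how large a document's
vocabulary is and how evenly it is used. Both are captured by the entropy
of the document's word-frequency distribution. `entroread` computes, in
bits, the Shannon entropy

> H = −Σᵢ pᵢ log₂ pᵢ

and the full Rényi entropy spectrum

> H_α = log₂(Σᵢ pᵢ^α) / (1 − α)

over a grid of orders (default α ∈ [0, 2] in steps of 0.1, Shannon
substituted at α = 1). Low orders weight vocabulary breadth (α = 0 is
log₂ of the vocabulary size), high orders weight the dominant words, so
the spectrum separates "uses many words" from "uses common words
unevenly".

Around the estimators the package provides the comparative machinery of a
paired readability study:

* **Corpus handling** — manifest-driven ingestion of pre-tokenized text
  with group/pair/section metadata, Unicode-aware token cleaning,
  frequency tables (`read_corpus()`, `build_frequency_table()`).
* **Spectra** — `entropy_spectra()`, `entropy_spectrum()`,
  `word_contributions()`, plot methods.
* **Paired comparison** — per-order Wilcoxon signed-rank tests with exact
  tie-aware p-values for ≤ 25 informative pairs
  (`paired_test_table()`), ROC discrimination with rank-based AUC and
  Youden-J cutoffs (`roc_table()`).
* **Length control** — fixed-size random subsampling
  (`run_random_experiment()`), which removes the document-length artefact
  that inflates raw α = 0 comparisons.
* **Section profiles and term density** — per-section entropy gaps
  (`section_delta_table()`), technical-term density against a lexicon and
  its Spearman correlation with entropy (`tt_density()`,
  `tt_entropy_correlation()`).
* **Grade benchmarking** — quartile summaries and Mann–Whitney band
  assignment against grade-level corpora (`grade_summary()`,
  `assign_band()`).
* **Synthetic corpora** — Zipf–Mandelbrot document generators with
  closed-form true entropies, used for all validation
  (`generate_paired_corpus()`, `generate_grade_corpus()`,
  `true_entropy()`).
* **Pipeline** — `run_full_analysis()` runs every applicable stage on a
  corpus and returns a report object with `print()`, `tidy()`,
  `glance()`, `autoplot()` and `write_report()` methods.

Everything is tidyverse-native: corpora and results are tibbles, and the
report object follows broom conventions.

## Worked example

Real consent-form corpora are confidential, so the example uses the
built-in synthetic generator: 17 pairs, guardian versions drawn from a
richer Zipf–Mandelbrot vocabulary (V = 2000, 6000 tokens) than minor
versions (V = 800, 1700 tokens).

```r
library(entroread)

corpus  <- generate_paired_corpus(paired_corpus_spec(), seed = 42)
spectra <- entropy_spectra(corpus, grid = report_alphas())
head(dplyr::arrange(spectra, alpha, group, doc_id), 4)
#> # A tibble: 4 × 7
#>   doc_id       group    pair_id n_tokens alpha entropy_bits estimator
#>   <chr>        <chr>    <chr>      <int> <dbl>        <dbl> <chr>
#> 1 p01_guardian guardian p01         6000     0         10.3 renyi
#> 2 p02_guardian guardian p02         6000     0         10.3 renyi
#> 3 p03_guardian guardian p03         6000     0         10.3 renyi
#> 4 p04_guardian guardian p04         6000     0         10.2 renyi

paired_test_table(paired_deltas(spectra))
#> # A tibble: 4 × 8
#>   alpha n_used w_statistic   p_value n_positive n_negative n_zero method
#>   <dbl>  <int>       <dbl>     <dbl>      <int>      <int>  <int> <chr>
#> 1   0       17         153 0.0000153         17          0      0 exact
#> 2   0.5     17         153 0.0000153         17          0      0 exact
#> 3   1       17         153 0.0000153         17          0      0 exact
#> 4   1.5     17         153 0.0000153         17          0      0 exact

roc_table(spectra)
#> # A tibble: 4 × 7
#>   alpha   auc threshold sensitivity specificity youden_j positive_class
#>   <dbl> <dbl>     <dbl>       <dbl>       <dbl>    <dbl> <chr>
#> 1   0       1      9.55           1           1        1 guardian
#> 2   0.5     1      8.88           1           1        1 guardian
#> 3   1       1      7.95           1           1        1 guardian
#> 4   1.5     1      6.99           1           1        1 guardian
```

Every guardian version carries more lexical information than its minor
counterpart (17/17 positive differences, exact signed-rank
p = 1.5 × 10⁻⁵ at every order), and entropy separates the two groups
perfectly on this synthetic corpus (AUC = 1). The length-controlled
version of the same comparison — 100 random 1000-token subsamples per
document — confirms the gap is not a length artefact:

```r
run_random_experiment(corpus, grid = c(0, 1), sample_size = 1000,
                      iterations = 100, seed = 42)
#> # A tibble: 2 × 8
#>   alpha n_used w_statistic   p_value n_positive n_negative n_zero method
#>   <dbl>  <int>       <dbl>     <dbl>      <int>      <int>  <int> <chr>
#> 1     0     17         153 0.0000153         17          0      0 exact
#> 2     1     17         153 0.0000153         17          0      0 exact
```

On a *null* corpus (identical generators, tenfold length gap) the raw
α = 0 comparison is spuriously significant and the subsampled one is
not; this is verified across 50 replicate corpora by the test suite.
`run_full_analysis()` wraps all stages, and the methods vignette
(`vignettes/entropy-readability.Rmd`) documents the model, the generator
defaults and every numerical convention.

## Tests

The suite is testthat (edition 3) and validates the numerics against
independent oracles: literal-summation entropy oracles on 1000 random
frequency tables, full 2ⁿ enumeration of the signed-rank null, brute-force
AUC pair counting, closed-form generator entropies at 200k tokens, and
replicated (50-corpus) checks of the paired, null, grade-band and
term-density pipelines.

```r
# from a source checkout
devtools::test()
# or against an installed copy
testthat::test_dir("tests/testthat", package = "entroread",
                   load_package = "installed")
```

## License

MIT. See `LICENSE`.
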