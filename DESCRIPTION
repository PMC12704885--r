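Package: entroread
Title: Entropy-Based Lexical Readability Analysis of Paired Document Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the lexical complexity of tokenized documents with the
    Shannon and Renyi entropy family and compares paired document versions
    (for example simplified minor-version and full guardian-version informed
    consent forms) and grade-level reference corpora. Provides frequency-table
    construction from pre-segmented token streams, entropy spectra over a grid
    of Renyi orders, paired Wilcoxon signed-rank analysis with exact small-sample
    p-values, rank-based ROC discrimination with Youden cutoffs, fixed-size
    token subsampling to control for document length, section-wise entropy
    decomposition, technical-term density, grade-band assignment, and a
    Zipf-Mandelbrot synthetic-corpus generator with closed-form true entropies
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
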