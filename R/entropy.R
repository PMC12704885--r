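#' Default Renyi-order grid
#'
#' Orders 0 to 2 in steps of 0.1, the full sweep used for the
#' sensitivity curve; [report_alphas()] is the reduced set used in the
#' headline tables.
#'
#' @return Numeric vector of alpha values.
#' @export
default_alpha_grid <- function() {
  round(seq(0, 2, by = 0.1), 10)
}

#' @rdname default_alpha_grid
#' @export
report_alphas <- function() {
  c(0, 0.5, 1, 1.5)
}

as_prob_vector <- function(table) {
  if (is.data.frame(table)) {
    check_prob_column(table)
    p <- table$prob
  } else if (is.numeric(table)) {
    p <- table
  } else {
    abort("`table` must be a frequency table or a numeric probability vector")
  }
  if (any(p <= 0)) {
    abort("all probabilities must be strictly positive")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort("probabilities must sum to 1")
  }
  p
}

#' Shannon entropy of a frequency table
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} in bits, the plug-in estimate from
#' relative frequencies. Higher values mean a larger vocabulary and a more
#' even word-frequency distribution, i.e. a lexically harder text.
#'
#' @param table A `freq_table` (or a numeric probability vector).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
#' @export
shannon_entropy <- function(table) {
  p <- as_prob_vector(table)
  -sum(p * log2(p))
}

#' Renyi entropy of order alpha
#'
#' \eqn{H_\alpha = \log_2(\sum_i p_i^\alpha) / (1 - \alpha)} in bits.
#' At `alpha = 0` this is the Hartley entropy \eqn{\log_2 n} (vocabulary
#' size only); small alpha weights the size of the word set, large alpha
#' weights the frequent words. `alpha = 1` is rejected here — the family's
#' limit there is [shannon_entropy()], and [entropy_spectrum()] substitutes
#' it automatically.
#'
#' @param table A `freq_table` (or numeric probability vector).
#' @param alpha Renyi order, `alpha >= 0`, `alpha != 1`.
#' @return Entropy in bits.
#' @examples
#' renyi_entropy(c(0.5, 0.25, 0.25), alpha = 0) # log2(3)
#' @export
renyi_entropy <- function(table, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha)) {
    abort("`alpha` must be a single number")
  }
  if (alpha < 0) {
    abort("`alpha` must be non-negative")
  }
  if (abs(alpha - 1) < 1e-9) {
    abort("alpha = 1 is the Shannon limit; call shannon_entropy()")
  }
  p <- as_prob_vector(table)
  if (is.infinite(alpha)) {
    return(-log2(max(p)))
  }
  if (alpha == 0) {
    return(log2(length(p)))
  }
  log2(sum(p^alpha)) / (1 - alpha)
}

#' Min-entropy (Renyi order infinity)
#'
#' \eqn{H_\infty = -\log_2 p_{max}}: driven entirely by the single most
#' frequent word.
#'
#' @inheritParams shannon_entropy
#' @return Entropy in bits.
#' @export
min_entropy <- function(table) {
  p <- as_prob_vector(table)
  -log2(max(p))
}

#' Entropy spectrum over a grid of Renyi orders
#'
#' Evaluates the entropy family on `grid`, substituting Shannon entropy at
#' `alpha = 1` (and within a 1e-9 band of it) to avoid the removable
#' singularity.
#'
#' @inheritParams shannon_entropy
#' @param grid Sorted distinct non-negative alpha values;
#'   [default_alpha_grid()] by default.
#' @return A tibble with columns `alpha`, `entropy_bits`, `estimator`
#'   (`"shannon"` or `"renyi"`).
#' @export
entropy_spectrum <- function(table, grid = default_alpha_grid()) {
  if (length(grid) == 0) {
    abort("`grid` must contain at least one alpha value")
  }
  if (any(grid < 0) || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be sorted, distinct and non-negative")
  }
  p <- as_prob_vector(table)
  is_shannon <- abs(grid - 1) < 1e-9
  vals <- vapply(seq_along(grid), function(i) {
    if (is_shannon[i]) shannon_entropy(p) else renyi_entropy(p, grid[i])
  }, numeric(1))
  tibble(
    alpha = as.numeric(grid),
    entropy_bits = vals,
    estimator = ifelse(is_shannon, "shannon", "renyi")
  )
}

#' Per-document entropy spectra for a corpus
#'
#' Builds a frequency table per document and evaluates [entropy_spectrum()]
#' on each.
#'
#' @param corpus A corpus tibble (see [read_corpus()]) with a `tokens`
#'   list-column.
#' @param grid Alpha grid, as in [entropy_spectrum()].
#' @return A tibble of class `entropy_spectra` with columns `doc_id`,
#'   `group`, `pair_id`, `n_tokens`, `alpha`, `entropy_bits`, `estimator`.
#' @export
entropy_spectra <- function(corpus, grid = default_alpha_grid()) {
  if (!is.data.frame(corpus) || !"tokens" %in% names(corpus)) {
    abort("`corpus` must be a corpus tibble with a `tokens` list-column")
  }
  out <- purrr::map2(corpus$doc_id, corpus$tokens, function(id, toks) {
    sp <- entropy_spectrum(build_frequency_table(toks), grid)
    sp$doc_id <- id
    sp
  })
  out <- dplyr::bind_rows(out)
  meta <- tibble(
    doc_id = corpus$doc_id,
    group = if ("group" %in% names(corpus)) corpus$group else NA_character_,
    pair_id = if ("pair_id" %in% names(corpus)) corpus$pair_id else NA_character_,
    n_tokens = lengths(corpus$tokens)
  )
  out <- dplyr::left_join(out, meta, by = "doc_id")
  out <- out[, c("doc_id", "group", "pair_id", "n_tokens",
                 "alpha", "entropy_bits", "estimator")]
  class(out) <- c("entropy_spectra", class(out))
  out
}

#' Per-word Shannon entropy contributions
#'
#' Decomposes Shannon entropy into its per-word terms
#' \eqn{-p_i \log_2 p_i}; the terms sum to the document's Shannon entropy.
#' Used to show which words carry the information mass (the Renyi family
#' has no such additive decomposition).
#'
#' @inheritParams shannon_entropy
#' @return A tibble with columns `token`, `prob`, `contribution_bits`,
#'   ordered by decreasing probability.
#' @export
word_contributions <- function(table) {
  check_prob_column(table)
  out <- tibble(
    token = table$token,
    prob = table$prob,
    contribution_bits = -table$prob * log2(table$prob)
  )
  dplyr::arrange(out, dplyr::desc(.data$prob), .data$token)
}

#' Write entropy spectra as TSV
#'
#' @param spectra An `entropy_spectra` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  readr::write_tsv(
    spectra[, c("doc_id", "alpha", "entropy_bits", "estimator")],
    path, progress = FALSE
  )
  invisible(path)
}
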