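#' Quartile summary per document group
#'
#' Word count and every entropy order summarised as 25th percentile, median
#' and 75th percentile within each group — the descriptive table of a
#' corpus.
#'
#' @param spectra An `entropy_spectra` tibble.
#' @return A tibble with columns `group`, `metric` (`"word_count"` or
#'   `"entropy"`), `alpha` (`NA` for word count), `n_docs`, `q25`, `median`,
#'   `q75`.
#' @export
grade_summary <- function(spectra) {
  if (nrow(spectra) == 0) {
    abort("`spectra` is empty")
  }
  wc <- dplyr::distinct(spectra, .data$group, .data$doc_id, .data$n_tokens)
  wc_sum <- dplyr::summarise(
    dplyr::group_by(wc, .data$group),
    metric = "word_count", alpha = NA_real_, n_docs = dplyr::n(),
    q25 = unname(quantile(.data$n_tokens, 0.25)),
    median = unname(median(.data$n_tokens)),
    q75 = unname(quantile(.data$n_tokens, 0.75)),
    .groups = "drop"
  )
  ent_sum <- dplyr::summarise(
    dplyr::group_by(spectra, .data$group, .data$alpha),
    metric = "entropy", n_docs = dplyr::n(),
    q25 = unname(quantile(.data$entropy_bits, 0.25)),
    median = unname(median(.data$entropy_bits)),
    q75 = unname(quantile(.data$entropy_bits, 0.75)),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(wc_sum, ent_sum)
  out[, c("group", "metric", "alpha", "n_docs", "q25", "median", "q75")]
}

#' Unpaired comparison of a target sample against one grade corpus
#'
#' Two-sided Mann-Whitney rank-sum test (midranks; exact when sample sizes
#' permit and no ties, otherwise normal approximation with continuity
#' correction) plus the sign of the median difference.
#'
#' @param target_values,grade_values Numeric vectors of per-document
#'   entropies.
#' @return A one-row tibble: `p_value`, `direction`
#'   (sign of `median(target) - median(grade)`), `n_target`, `n_grade`.
#' @export
compare_to_grade <- function(target_values, grade_values) {
  if (length(target_values) == 0 || length(grade_values) == 0) {
    abort("both samples must be non-empty")
  }
  wt <- suppressWarnings(
    wilcox.test(target_values, grade_values, alternative = "two.sided",
                correct = TRUE)
  )
  tibble(
    p_value = wt$p.value,
    direction = sign(median(target_values) - median(grade_values)),
    n_target = length(target_values),
    n_grade = length(grade_values)
  )
}

#' Assign a readability grade band by entropy
#'
#' For each alpha, compares the target group's per-document entropies with
#' each grade-level reference corpus and collects the grades that are not
#' significantly different at `level` — the grade band. An empty band falls
#' back to the nearest grade by absolute median difference, flagged
#' `"above"` or `"below"` when the target median lies outside the whole
#' grade range. Band membership is absence of evidence for a difference,
#' not demonstrated equivalence.
#'
#' @param spectra An `entropy_spectra` tibble containing the target group
#'   and at least two grade groups.
#' @param target_group Group label of the documents to place (default
#'   `"minor"`).
#' @param grade_groups Grade group labels present in `spectra`.
#' @param alphas Alpha values to assess (default [report_alphas()]).
#' @param level Significance level (default 0.05).
#' @return A tibble with one row per alpha: `alpha`, `band` (list of grade
#'   labels), `nearest_grade`, `flag` (`NA`, `"above"` or `"below"`), and
#'   `details` (list of per-grade tibbles with `grade`, `p_value`,
#'   `direction`, `median_diff`).
#' @export
assign_band <- function(spectra, target_group = "minor",
                        grade_groups = c("grade2", "grade6", "grade9"),
                        alphas = report_alphas(), level = 0.05) {
  present <- intersect(grade_groups, unique(spectra$group))
  if (length(present) < 2) {
    abort("need at least 2 grade corpora in `spectra`")
  }
  if (!target_group %in% spectra$group) {
    abort(paste0("target group not in spectra: ", target_group))
  }
  rows <- purrr::map(alphas, function(a) {
    sl <- dplyr::filter(spectra, abs(.data$alpha - a) < 1e-9)
    if (nrow(sl) == 0) {
      abort(paste0("alpha ", a, " not present in spectra"))
    }
    tv <- sl$entropy_bits[sl$group == target_group]
    det <- dplyr::bind_rows(purrr::map(present, function(g) {
      gv <- sl$entropy_bits[sl$group == g]
      cmp <- compare_to_grade(tv, gv)
      cmp$grade <- g
      cmp$median_diff <- median(tv) - median(gv)
      cmp
    }))
    det <- det[, c("grade", "p_value", "direction", "median_diff",
                   "n_target", "n_grade")]
    band <- det$grade[det$p_value > level]
    nearest <- det$grade[which.min(abs(det$median_diff))]
    flag <- NA_character_
    if (length(band) == 0) {
      if (all(det$median_diff > 0)) flag <- "above"
      if (all(det$median_diff < 0)) flag <- "below"
    }
    tibble(alpha = a, band = list(band), nearest_grade = nearest,
           flag = flag, details = list(det))
  })
  dplyr::bind_rows(rows)
}
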