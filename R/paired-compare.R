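#' Paired entropy differences (guardian minus minor)
#'
#' Joins the two members of every pair on the alpha grid and computes
#' \eqn{\Delta = H_{guardian} - H_{minor}} per pair and order.
#'
#' @param spectra An `entropy_spectra` tibble carrying `group` and `pair_id`
#'   for the `minor`/`guardian` documents.
#' @return A tibble with columns `pair_id`, `alpha`, `h_guardian`,
#'   `h_minor`, `delta`.
#' @export
paired_deltas <- function(spectra) {
  paired <- dplyr::filter(spectra, .data$group %in% c("minor", "guardian"))
  if (nrow(paired) == 0) {
    abort("no minor/guardian documents in `spectra`")
  }
  if (any(is.na(paired$pair_id) | !nzchar(paired$pair_id))) {
    abort("paired documents lack a pair_id")
  }
  grids <- dplyr::summarise(
    dplyr::group_by(paired, .data$pair_id, .data$group),
    grid = paste(sort(.data$alpha), collapse = ","), .groups = "drop"
  )
  counts <- dplyr::count(dplyr::distinct(paired, .data$pair_id, .data$group,
                                         .data$doc_id),
                         .data$pair_id, .data$group)
  bad_n <- unique(counts$pair_id[counts$n != 1])
  complete <- dplyr::count(dplyr::distinct(grids, .data$pair_id, .data$group),
                           .data$pair_id)
  bad_n <- union(bad_n, complete$pair_id[complete$n != 2])
  if (length(bad_n) > 0) {
    abort(paste0("incomplete pair(s): ", paste(sort(bad_n), collapse = ", ")))
  }
  gchk <- dplyr::summarise(dplyr::group_by(grids, .data$pair_id),
                           ok = dplyr::n_distinct(.data$grid) == 1,
                           .groups = "drop")
  if (any(!gchk$ok)) {
    abort(paste0("mismatched alpha grids for pair(s): ",
                 paste(gchk$pair_id[!gchk$ok], collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    paired[, c("pair_id", "group", "alpha", "entropy_bits")],
    names_from = "group", values_from = "entropy_bits"
  )
  tibble(
    pair_id = wide$pair_id,
    alpha = wide$alpha,
    h_guardian = wide$guardian,
    h_minor = wide$minor,
    delta = wide$guardian - wide$minor
  )
}

# Exact null distribution of the signed-rank statistic W+ on doubled midranks
# (doubling makes tied midranks integral), as counts over 0..sum(2r).
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- numeric(total + 1)
    g[(r + 1):(total + 1)] <- f[1:(total + 1 - r)]
    f <- f + g
  }
  f
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are discarded before ranking (Wilcoxon's method), tied
#' absolute differences receive midranks, and the two-sided p-value is the
#' doubled smaller tail of W+ (capped at 1). For `n_used <= 25` the null
#' distribution is computed exactly by convolution over sign assignments —
#' valid with ties, unlike the textbook tables; larger samples use the
#' normal approximation with continuity and tie correction.
#'
#' @param deltas Numeric vector of paired differences.
#' @param exact_limit Largest `n_used` for which the exact distribution is
#'   used (default 25).
#' @return A one-row tibble: `n_used`, `w_statistic` (W+), `p_value`,
#'   `n_positive`, `n_negative`, `n_zero`, `method`.
#' @examples
#' signed_rank_test(c(1, 2, 3, 4, 5)) # exact p = 0.0625
#' @export
signed_rank_test <- function(deltas, exact_limit = 25) {
  if (!is.numeric(deltas) || length(deltas) == 0) {
    abort("`deltas` must be a non-empty numeric vector")
  }
  n_positive <- sum(deltas > 0)
  n_negative <- sum(deltas < 0)
  n_zero <- sum(deltas == 0)
  d <- deltas[deltas != 0]
  if (length(d) == 0) {
    abort("no nonzero differences")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n <- length(d)
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(ranks2)
    total <- 2^n
    w2 <- round(2 * w)
    idx <- seq_along(counts) - 1
    p_lo <- sum(counts[idx <= w2 + 1e-9]) / total
    p_hi <- sum(counts[idx >= w2 - 1e-9]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  tibble(
    n_used = n, w_statistic = w, p_value = p,
    n_positive = n_positive, n_negative = n_negative, n_zero = n_zero,
    method = method
  )
}

#' Signed-rank test per Renyi order
#'
#' Applies [signed_rank_test()] to the paired differences at every alpha:
#' the per-order test table of the paired analysis (p-value plus
#' positive/negative sign counts).
#'
#' @param deltas Output of [paired_deltas()].
#' @return A tibble with one row per alpha: `alpha`, `n_used`,
#'   `w_statistic`, `p_value`, `n_positive`, `n_negative`, `n_zero`,
#'   `method`.
#' @export
paired_test_table <- function(deltas) {
  out <- dplyr::group_modify(
    dplyr::group_by(deltas, .data$alpha),
    function(df, key) signed_rank_test(df$delta)
  )
  dplyr::ungroup(out)
}

#' Rank-based AUC for a single entropy feature
#'
#' The probability that a randomly chosen guardian value exceeds a randomly
#' chosen minor value (ties count one half): the Mann-Whitney pair-counting
#' statistic. For a single monotone feature this equals the ROC area of a
#' logistic-regression score on that feature, so no model is fitted.
#'
#' @param minor_values,guardian_values Numeric vectors of the feature in the
#'   two classes (guardian is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(minor_values, guardian_values) {
  if (length(minor_values) == 0 || length(guardian_values) == 0) {
    abort("both value vectors must be non-empty")
  }
  r <- rank(c(minor_values, guardian_values))
  n_m <- length(minor_values)
  n_g <- length(guardian_values)
  rg <- sum(r[(n_m + 1):(n_m + n_g)])
  (rg - n_g * (n_g + 1) / 2) / (n_m * n_g)
}

#' Youden-optimal classification threshold
#'
#' Scans all candidate cutoffs — midpoints between adjacent distinct pooled
#' values plus the two infinite endpoints — classifying `value >= threshold`
#' as guardian, and returns the cutoff maximising Youden's
#' J = sensitivity + specificity - 1 (lowest threshold on ties).
#'
#' @inheritParams rank_auc
#' @return A one-row tibble: `auc`, `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`, `positive_class`.
#' @export
youden_threshold <- function(minor_values, guardian_values) {
  if (length(minor_values) == 0 || length(guardian_values) == 0) {
    abort("both value vectors must be non-empty")
  }
  v <- sort(unique(c(minor_values, guardian_values)))
  cand <- c(-Inf, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2, Inf)
  sens <- vapply(cand, function(t) mean(guardian_values >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(minor_values < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1] # candidates ascend, so first = lowest
  tibble(
    auc = rank_auc(minor_values, guardian_values),
    threshold = cand[best],
    sensitivity = sens[best],
    specificity = spec[best],
    youden_j = j[best],
    positive_class = "guardian"
  )
}

#' ROC discrimination table per Renyi order
#'
#' AUC and Youden cutoff for separating minor- from guardian-version
#' documents using the entropy at each alpha as the single feature.
#'
#' @param spectra An `entropy_spectra` tibble with `minor` and `guardian`
#'   documents.
#' @return A tibble with one row per alpha: `alpha`, `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `youden_j`, `positive_class`.
#' @export
roc_table <- function(spectra) {
  paired <- dplyr::filter(spectra, .data$group %in% c("minor", "guardian"))
  if (nrow(paired) == 0) {
    abort("no minor/guardian documents in `spectra`")
  }
  out <- dplyr::group_modify(
    dplyr::group_by(paired, .data$alpha),
    function(df, key) {
      youden_threshold(df$entropy_bits[df$group == "minor"],
                       df$entropy_bits[df$group == "guardian"])
    }
  )
  dplyr::ungroup(out)
}

#' Spearman rank correlation
#'
#' Midrank-based Spearman rho with a two-sided p-value (via
#' [stats::cor.test()]; the t approximation is used when ties are present).
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length")
  }
  if (length(x) < 3) {
    abort("need at least 3 observations")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("undefined correlation: an input vector is constant")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
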