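spectra_at <- function(spectra, alphas) {
  keep <- vapply(spectra$alpha, function(a) any(abs(a - alphas) < 1e-9),
                 logical(1))
  out <- spectra[keep, ]
  class(out) <- class(spectra)
  out
}

has_pairs <- function(corpus) {
  paired <- dplyr::filter(corpus, .data$group %in% c("minor", "guardian"))
  nrow(paired) > 0 &&
    !any(is.na(paired$pair_id) | !nzchar(paired$pair_id)) &&
    tryCatch({check_pairing(paired); TRUE}, error = function(e) FALSE)
}

skipped <- function(reason) {
  structure(list(skipped = TRUE, reason = reason), class = "skipped_stage")
}

default_config <- function() {
  list(
    corpus = NULL,
    manifest = NULL,
    alphas = report_alphas(),
    grid = default_alpha_grid(),
    lexicon = NULL,
    tt_alpha = 1.5,
    subsample = list(sample_size = 1000, iterations = 100, replace = "auto"),
    target_group = "minor",
    grade_groups = c("grade2", "grade6", "grade9"),
    level = 0.05,
    seed = 1L
  )
}

#' Run the full entropy readability analysis
#'
#' Orchestrates ingest, entropy spectra, the paired signed-rank and ROC
#' analyses, section-wise differences, the length-controlled subsampling
#' experiment, grade-band assignment and the technical-term correlation as
#' one reproducible run. Every table is computed by the corresponding
#' exported function — the orchestrator itself computes nothing — and
#' stages whose inputs are absent (no pairs, no sections, no lexicon, no
#' grade corpora) are recorded as skipped with a reason rather than
#' failing.
#'
#' @param config A named list; unknown keys are an error. Keys (all
#'   optional except one of `corpus`/`manifest`): `corpus` (a corpus
#'   tibble), `manifest` (path, read with [read_corpus()]), `alphas`
#'   (reported orders, default [report_alphas()]), `grid` (full sweep for
#'   the sensitivity curve), `lexicon` (character vector or lexicon file
#'   path), `tt_alpha`, `subsample` (list with `sample_size`, `iterations`,
#'   `replace`), `target_group`, `grade_groups`, `level`, `seed`.
#' @return An object of class `analysis_report`: a list with elements
#'   `descriptives`, `paired_tests`, `roc`, `section_deltas`,
#'   `random_experiment`, `grade_bands`, `tt_correlation`, `spectra`,
#'   `deltas` and `run_record`. See [tidy.analysis_report()].
#' @export
run_full_analysis <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)

  corpus <- cfg$corpus
  if (is.null(corpus)) {
    if (is.null(cfg$manifest)) {
      abort("config must supply `corpus` or `manifest`")
    }
    corpus <- read_corpus(cfg$manifest)
  }
  lexicon <- cfg$lexicon
  if (is.character(lexicon) && length(lexicon) == 1 && file.exists(lexicon)) {
    lexicon <- read_lexicon(lexicon)
  }

  full_grid <- sort(unique(round(c(cfg$grid, cfg$alphas), 9)))
  spectra <- entropy_spectra(corpus, grid = full_grid)
  spectra_rep <- spectra_at(spectra, cfg$alphas)

  descriptives <- grade_summary(spectra_rep)

  pairs_ok <- has_pairs(corpus)
  deltas <- if (pairs_ok) paired_deltas(spectra) else NULL
  paired_tests <- if (pairs_ok) {
    paired_test_table(paired_deltas(spectra_rep))
  } else {
    skipped("no complete minor/guardian pairs in corpus")
  }
  roc <- if (pairs_ok) {
    roc_table(spectra_rep)
  } else {
    skipped("no complete minor/guardian pairs in corpus")
  }

  paired_docs <- dplyr::filter(corpus, .data$group %in% c("minor", "guardian"))
  has_sections <- pairs_ok && nrow(paired_docs) > 0 &&
    all(!vapply(paired_docs$sections, is.null, logical(1)))
  section_deltas <- if (has_sections) {
    section_delta_table(corpus, alphas = cfg$alphas)
  } else {
    skipped("paired documents lack section annotations")
  }

  random_experiment <- if (pairs_ok) {
    run_random_experiment(
      corpus, grid = cfg$alphas,
      sample_size = cfg$subsample$sample_size,
      iterations = cfg$subsample$iterations,
      replace = cfg$subsample$replace,
      seed = cfg$seed
    )
  } else {
    skipped("no complete minor/guardian pairs in corpus")
  }

  grades_present <- intersect(cfg$grade_groups, unique(corpus$group))
  grade_bands <- if (length(grades_present) >= 2 &&
                     cfg$target_group %in% corpus$group) {
    assign_band(spectra_rep, target_group = cfg$target_group,
                grade_groups = grades_present, alphas = cfg$alphas,
                level = cfg$level)
  } else {
    skipped("need a target group and at least 2 grade corpora")
  }

  tt_correlation <- if (!is.null(lexicon) && nrow(corpus) >= 3) {
    tt_entropy_correlation(corpus, lexicon, alpha = cfg$tt_alpha)
  } else {
    skipped("no lexicon supplied (or fewer than 3 documents)")
  }

  run_record <- list(
    config = cfg[setdiff(names(cfg), c("corpus", "lexicon"))],
    n_docs = nrow(corpus),
    groups = sort(unique(corpus$group)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("entroread")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  structure(
    list(
      descriptives = descriptives,
      paired_tests = paired_tests,
      roc = roc,
      section_deltas = section_deltas,
      random_experiment = random_experiment,
      grade_bands = grade_bands,
      tt_correlation = tt_correlation,
      spectra = spectra,
      deltas = deltas,
      run_record = run_record
    ),
    class = "analysis_report"
  )
}

report_tables <- function() {
  c("descriptives", "paired_tests", "roc", "section_deltas",
    "random_experiment", "grade_bands", "tt_correlation", "spectra",
    "deltas")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  documents:", x$run_record$n_docs,
      "| groups:", paste(x$run_record$groups, collapse = ", "), "\n")
  cat("  seed:", x$run_record$seed, "\n")
  for (nm in report_tables()) {
    el <- x[[nm]]
    if (inherits(el, "skipped_stage")) {
      cat(sprintf("  %-18s skipped (%s)\n", nm, el$reason))
    } else if (is.data.frame(el)) {
      cat(sprintf("  %-18s %d x %d\n", nm, nrow(el), ncol(el)))
    }
  }
  invisible(x)
}

#' Tidy a table out of an analysis report
#'
#' @param x An `analysis_report`.
#' @param table Which table to return (see [run_full_analysis()]); default
#'   `"paired_tests"`.
#' @param ... Unused.
#' @return A tibble; an error if the requested stage was skipped.
#' @method tidy analysis_report
#' @export
tidy.analysis_report <- function(x, table = "paired_tests", ...) {
  table <- match.arg(table, report_tables())
  el <- x[[table]]
  if (inherits(el, "skipped_stage")) {
    abort(paste0("stage `", table, "` was skipped: ", el$reason))
  }
  as_tibble(el)
}

#' One-row summary of an analysis report
#'
#' @param x An `analysis_report`.
#' @param ... Unused.
#' @return A one-row tibble with corpus size, group count, alphas, seed and
#'   the number of computed (non-skipped) tables.
#' @method glance analysis_report
#' @export
glance.analysis_report <- function(x, ...) {
  computed <- sum(vapply(report_tables(), function(nm) {
    is.data.frame(x[[nm]])
  }, logical(1)))
  tibble(
    n_docs = x$run_record$n_docs,
    n_groups = length(x$run_record$groups),
    alphas = paste(x$run_record$config$alphas, collapse = ","),
    seed = x$run_record$seed,
    n_tables = computed
  )
}

#' Write an analysis report to disk
#'
#' Tables as TSV plus the run record as JSON; output is written to a
#' temporary directory and renamed into place so a failed run never leaves
#' a partial report.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  tmp <- paste0(dir, ".tmp")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  for (nm in report_tables()) {
    el <- report[[nm]]
    if (is.data.frame(el)) {
      flat <- el
      for (col in names(flat)) {
        if (is.list(flat[[col]])) {
          flat[[col]] <- vapply(flat[[col]], function(v) {
            if (is.data.frame(v)) {
              jsonlite::toJSON(v, auto_unbox = TRUE)
            } else {
              paste(v, collapse = ",")
            }
          }, character(1))
        }
      }
      readr::write_tsv(flat, file.path(tmp, paste0(nm, ".tsv")),
                       progress = FALSE)
    } else if (inherits(el, "skipped_stage")) {
      readr::write_lines(paste0("skipped: ", el$reason),
                         file.path(tmp, paste0(nm, ".skipped.txt")))
    }
  }
  jsonlite::write_json(report$run_record, file.path(tmp, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(dir, recursive = TRUE)
  file.rename(tmp, dir)
  invisible(dir)
}
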