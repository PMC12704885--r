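#' Groups recognised in a corpus manifest
#'
#' Document groups carried by a corpus: the two members of a consent-form pair
#' (`minor`, `guardian`), the three grade-level reference corpora, and a
#' catch-all `other`.
#'
#' @export
corpus_groups <- function() {
  c("minor", "guardian", "grade2", "grade6", "grade9", "other")
}

#' Drop non-lexical tokens from a segmented token stream
#'
#' Applies the cleaning rule used throughout the package: tokens are
#' NFC-normalised, then any token consisting solely of punctuation, symbols
#' and whitespace (Unicode categories P*, S* plus whitespace, optionally
#' extended with `extra_punct` characters) is removed. Word order is
#' preserved, so the result is still a token sequence, not a bag.
#'
#' @param tokens Character vector of raw segmented tokens.
#' @param extra_punct Optional character vector of additional characters to
#'   treat as punctuation.
#' @param drop Optional character vector of exact tokens to drop (for example
#'   numerals, if a study excludes them).
#' @return Character vector of retained, NFC-normalised tokens.
#' @examples
#' filter_tokens(c("informed", "consent", ",", "."))
#' @export
filter_tokens <- function(tokens, extra_punct = NULL, drop = NULL) {
  if (!is.character(tokens)) {
    abort("`tokens` must be a character vector")
  }
  out <- stringi::stri_trans_nfc(tokens)
  # keep a token iff it contains at least one lexical character
  lexical <- stringi::stri_detect_regex(out, "[^\\p{P}\\p{S}\\s]")
  lexical[is.na(lexical)] <- FALSE
  if (!is.null(extra_punct)) {
    chars <- unlist(stringi::stri_split_boundaries(
      stringi::stri_trans_nfc(extra_punct), type = "character"
    ))
    cls <- paste0("[^\\p{P}\\p{S}\\s", stringi::stri_replace_all_regex(
      paste(chars, collapse = ""), "([\\\\\\[\\]^-])", "\\\\$1"
    ), "]")
    lex2 <- stringi::stri_detect_regex(out, cls)
    lex2[is.na(lex2)] <- FALSE
    lexical <- lexical & lex2
  }
  out <- out[lexical & nzchar(out)]
  if (!is.null(drop)) {
    out <- out[!out %in% stringi::stri_trans_nfc(drop)]
  }
  if (length(out) == 0) {
    abort("document has no lexical content after filtering",
          class = "entroread_no_lexical_content")
  }
  out
}

#' Build a token frequency table
#'
#' Counts exact token multiplicities and derives the empirical distribution
#' \eqn{p_i = c_i / N} that every entropy in the package consumes.
#'
#' @param tokens Character vector of (already filtered) tokens.
#' @return A tibble of class `freq_table` with columns `token`, `count`,
#'   `prob`, ordered by decreasing count (ties broken by token). `sum(count)`
#'   is the document length N; `nrow()` is the vocabulary size.
#' @examples
#' build_frequency_table(c("a", "b", "a"))
#' @export
build_frequency_table <- function(tokens) {
  if (length(tokens) == 0) {
    abort("cannot build a frequency table from an empty token sequence")
  }
  if (!is.character(tokens)) {
    abort("`tokens` must be a character vector")
  }
  counts <- table(tokens)
  tbl <- tibble(
    token = names(counts),
    count = as.integer(counts)
  )
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$count), .data$token)
  tbl$prob <- tbl$count / sum(tbl$count)
  class(tbl) <- c("freq_table", class(tbl))
  tbl
}

#' Read a corpus from a manifest
#'
#' The manifest is a TSV with columns `doc_id`, `path`, `group` and
#' optionally `pair_id` and `section_file`. Paths are resolved relative to
#' the manifest's directory. Token files hold whitespace- or
#' newline-delimited pre-segmented tokens; raw-text files are passed through
#' the `segmenter` adapter first.
#'
#' @param manifest Path to the manifest TSV.
#' @param pretokenized If `TRUE` (default) referenced files are token files;
#'   otherwise each file's raw text is passed to `segmenter`.
#' @param segmenter A function `function(text) -> character vector of tokens`
#'   used only when `pretokenized = FALSE`. Word segmentation itself is
#'   deliberately pluggable so the pipeline stays segmenter-free and
#'   reproducible.
#' @param require_pairs If `TRUE`, every `minor`/`guardian` document must
#'   carry a `pair_id` matched by exactly one document of the opposite
#'   version.
#' @param extra_punct,drop Passed to [filter_tokens()].
#' @return A corpus tibble with columns `doc_id`, `group`, `pair_id`,
#'   `n_tokens`, and list-columns `tokens` and `sections` (each section entry
#'   a tibble with `section`, `start`, `end` token spans, or `NULL`).
#' @export
read_corpus <- function(manifest, pretokenized = TRUE, segmenter = NULL,
                        require_pairs = FALSE, extra_punct = NULL,
                        drop = NULL) {
  if (!file.exists(manifest)) {
    abort(paste0("manifest not found: ", manifest))
  }
  man <- readr::read_tsv(manifest, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("doc_id", "path", "group")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(man$doc_id)) {
    dup <- unique(man$doc_id[duplicated(man$doc_id)])
    abort(paste0("duplicate doc_id in manifest: ",
                 paste(dup, collapse = ", ")))
  }
  bad_group <- setdiff(unique(man$group), corpus_groups())
  if (length(bad_group) > 0) {
    abort(paste0("unknown group(s) in manifest: ",
                 paste(bad_group, collapse = ", "),
                 "; expected one of ", paste(corpus_groups(), collapse = ", ")))
  }
  base <- dirname(manifest)
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  paths <- resolve(man$path)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    abort(paste0("referenced file(s) not found: ",
                 paste(absent, collapse = ", ")))
  }
  if (!pretokenized && !is.function(segmenter)) {
    abort("`segmenter` must be a function when `pretokenized = FALSE`")
  }

  read_doc_tokens <- function(path, doc_id) {
    txt <- tryCatch(
      readr::read_file(path),
      error = function(e) abort(paste0("cannot decode ", path, " as UTF-8"))
    )
    if (!stringi::stri_enc_isutf8(txt)) {
      abort(paste0("file is not valid UTF-8: ", path))
    }
    raw_tokens <- if (pretokenized) {
      unlist(stringi::stri_split_regex(txt, "\\s+", omit_empty = TRUE))
    } else {
      segmenter(txt)
    }
    tryCatch(
      filter_tokens(raw_tokens, extra_punct = extra_punct, drop = drop),
      entroread_no_lexical_content = function(e) {
        abort(paste0("document has no lexical content: ", doc_id,
                     " (", path, ")"),
              class = "entroread_no_lexical_content")
      }
    )
  }

  tokens <- purrr::map2(paths, man$doc_id, read_doc_tokens)
  n_tokens <- lengths(tokens)

  sections <- vector("list", nrow(man))
  if ("section_file" %in% names(man)) {
    for (i in seq_len(nrow(man))) {
      sf <- man$section_file[i]
      if (!is.na(sf) && nzchar(sf)) {
        sp <- resolve(sf)
        if (!file.exists(sp)) {
          abort(paste0("section file not found: ", sp))
        }
        sec <- readr::read_tsv(sp, col_types = "cii", progress = FALSE)
        validate_sections(sec, n_tokens[i], man$doc_id[i])
        sections[[i]] <- sec
      }
    }
  }

  corpus <- tibble(
    doc_id = man$doc_id,
    group = man$group,
    pair_id = if ("pair_id" %in% names(man)) man$pair_id else NA_character_,
    n_tokens = as.integer(n_tokens),
    tokens = tokens,
    sections = sections
  )
  if (require_pairs) {
    check_pairing(corpus)
  }
  corpus
}

validate_sections <- function(sec, n_tokens, doc_id) {
  if (!all(c("section", "start", "end") %in% names(sec))) {
    abort(paste0("section file for ", doc_id,
                 " must have columns section, start, end"))
  }
  if (any(sec$start < 1) || any(sec$end > n_tokens) ||
      any(sec$start > sec$end)) {
    abort(paste0("section spans out of bounds for ", doc_id))
  }
  o <- order(sec$start)
  if (any(sec$end[o][-nrow(sec)] >= sec$start[o][-1])) {
    abort(paste0("section spans overlap for ", doc_id))
  }
  invisible(sec)
}

check_pairing <- function(corpus, call = rlang::caller_env()) {
  paired <- dplyr::filter(corpus, .data$group %in% c("minor", "guardian"))
  if (any(is.na(paired$pair_id) | !nzchar(paired$pair_id))) {
    bad <- paired$doc_id[is.na(paired$pair_id) | !nzchar(paired$pair_id)]
    abort(paste0("paired documents lack a pair_id: ",
                 paste(bad, collapse = ", ")), call = call)
  }
  tab <- dplyr::count(paired, .data$pair_id, .data$group)
  wide <- tidyr::pivot_wider(tab, names_from = "group", values_from = "n",
                             values_fill = 0L)
  if (!"minor" %in% names(wide)) wide$minor <- 0L
  if (!"guardian" %in% names(wide)) wide$guardian <- 0L
  bad <- wide$pair_id[wide$minor != 1L | wide$guardian != 1L]
  if (length(bad) > 0) {
    abort(paste0("pair_id without exactly one minor and one guardian: ",
                 paste(bad, collapse = ", ")), call = call)
  }
  invisible(corpus)
}

#' Write / read a frequency table as TSV
#'
#' Plain-text round trip: counts are reproduced exactly and probabilities are
#' re-derived from counts on read.
#'
#' @param table A `freq_table` from [build_frequency_table()].
#' @param path Output TSV path.
#' @return `write_frequency_table()` returns `path` invisibly;
#'   `read_frequency_table()` returns a `freq_table` tibble.
#' @export
write_frequency_table <- function(table, path) {
  check_prob_column(table)
  readr::write_tsv(table[, c("token", "count", "prob")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cid", progress = FALSE)
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$count), .data$token)
  tbl$prob <- tbl$count / sum(tbl$count)
  class(tbl) <- c("freq_table", class(tbl))
  tbl
}

#' Read a technical-term lexicon
#'
#' One term per line, UTF-8; blank lines are dropped and terms are
#' NFC-normalised and de-duplicated. Multi-token terms are written with
#' single spaces between their tokens.
#'
#' @param path Lexicon file path.
#' @return Character vector of terms.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("lexicon file not found: ", path))
  }
  terms <- readr::read_lines(path, progress = FALSE)
  terms <- stringi::stri_trim_both(stringi::stri_trans_nfc(terms))
  unique(terms[nzchar(terms)])
}
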