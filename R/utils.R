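# Internal helpers shared across modules.

# Deterministic 31-bit integer mixing for seed substreams. Values stay below
# 2^31 so they are valid R RNG seeds on every platform.
MOD31 <- 2147483647

mix_seed <- function(a, b) {
  ((as.numeric(a) %% MOD31) * 48271 + as.numeric(b) + 1) %% MOD31
}

hash_string <- function(x) {
  ints <- utf8ToInt(x)
  h <- 7
  for (i in ints) h <- (h * 131 + i) %% MOD31
  h
}

# Substream seed for one document (and optionally one iteration) under a root
# seed: adding or removing other documents never perturbs this stream.
substream_seed <- function(root, doc_id, iteration = 0L) {
  as.integer(mix_seed(mix_seed(root, hash_string(doc_id)), iteration))
}

with_substream <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Entropy in bits of a positive count (or probability) vector at one Renyi
# order. alpha == 1 (within a 1e-9 guard band) is Shannon; alpha == 0 is the
# Hartley entropy log2 of the support size; alpha == Inf is min-entropy.
entropy_from_counts <- function(counts, alpha) {
  p <- counts / sum(counts)
  if (is.infinite(alpha)) {
    return(-log2(max(p)))
  }
  if (alpha == 0) {
    return(log2(length(p)))
  }
  if (abs(alpha - 1) < 1e-9) {
    return(-sum(p * log2(p)))
  }
  log2(sum(p^alpha)) / (1 - alpha)
}

check_prob_column <- function(tbl, call = rlang::caller_env()) {
  if (!is.data.frame(tbl) || !all(c("token", "count", "prob") %in% names(tbl))) {
    abort("expected a frequency table with columns `token`, `count`, `prob`",
          call = call)
  }
  if (nrow(tbl) == 0) {
    abort("frequency table is empty", call = call)
  }
  invisible(tbl)
}
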