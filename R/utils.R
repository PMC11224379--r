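# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never clobber the
# session's stream.
with_rng_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a 31-bit sub-seed from a base seed and arbitrary string/int tokens,
# so per-column streams (seed, library_id, b) are deterministic and distinct.
derive_seed <- function(seed, ...) {
  tokens <- list(...)
  h <- as.double(seed) %% 2147483647
  for (tk in tokens) {
    if (is.character(tk)) tk <- sum(utf8ToInt(tk) * seq_along(utf8ToInt(tk)))
    h <- (h * 48271 + as.double(tk) + 1) %% 2147483647
  }
  as.integer(h)
}

# Interval keys: coordinates are 0-based half-open throughout the package.
exon_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

intron_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

parse_region_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):([0-9]+)-([0-9]+)(?::([+-]))?$", key))
  do.call(rbind, lapply(m, function(x) {
    data.frame(
      chrom = x[2], start = as.integer(x[3]), end = as.integer(x[4]),
      strand = if (length(x) >= 5 && nzchar(x[5])) x[5] else NA_character_,
      stringsAsFactors = FALSE
    )
  }))
}

row_var <- function(x) {
  if (ncol(x) < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
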