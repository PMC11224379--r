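#' Construct a feature-by-sample count matrix with sample metadata
#'
#' Light container shared by the RIP-enrichment and exon-usage stages:
#' an integer matrix (features in rows, samples in columns) plus a sample
#' descriptor table. \code{arm} labels the comparison group (e.g. IP vs
#' control, or control vs knockdown); \code{pseudo_rep} indexes bootstrap
#' pseudo-replicates (0 for original libraries).
#'
#' @param counts numeric matrix of non-negative counts; rownames are feature
#'   IDs (intron or exon keys) and must be unique.
#' @param samples data.frame with one row per column of \code{counts} and at
#'   least columns \code{library_id} and \code{arm}; a \code{pseudo_rep}
#'   column is added (0) when absent.
#' @return a \code{count_matrix}: list(counts, samples).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("`counts` must carry unique feature rownames")
  }
  if (any(counts < 0)) stop("negative counts are not allowed")
  stopifnot(is.data.frame(samples), nrow(samples) == ncol(counts),
            all(c("library_id", "arm") %in% names(samples)))
  if (anyNA(samples$arm)) stop("every sample needs an arm label")
  if (is.null(samples$pseudo_rep)) samples$pseudo_rep <- 0L
  colnames(counts) <- paste0(samples$library_id,
                             ifelse(samples$pseudo_rep > 0,
                                    paste0(".b", samples$pseudo_rep), ""))
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples; arms:",
      paste(sprintf("%s=%d", names(table(x$samples$arm)),
                    table(x$samples$arm)), collapse = ", "), "\n")
  invisible(x)
}

#' Expand libraries into bootstrap pseudo-replicates by binomial thinning
#'
#' Each original column is replaced by \code{B} thinned copies in which every
#' count is an independent Binomial(n = count, p = fraction) draw. Thinning is
#' distribution-equivalent to subsampling the underlying reads at rate
#' \code{fraction} without carrying read identities, and is the device that
#' creates replicate spread when only one library per arm exists. Each
#' pseudo-replicate stream is seeded deterministically from
#' (seed, library_id, b), so results are reproducible column-by-column and
#' invariant to column order.
#'
#' @param cm a \code{count_matrix} of original libraries.
#' @param fraction subsampling rate in (0, 1]; at 1 every pseudo-replicate
#'   equals its source column exactly.
#' @param B number of pseudo-replicates per library (>= 2 for downstream
#'   testing).
#' @param seed integer base seed.
#' @return a \code{count_matrix} with B columns per input library and
#'   \code{pseudo_rep} set to 1..B.
#' @export
subsample_pseudoreplicates <- function(cm, fraction, B, seed) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]")
  }
  B <- as.integer(B)
  stopifnot(B >= 1L)
  n <- nrow(cm$counts)
  cols <- vector("list", ncol(cm$counts) * B)
  meta <- vector("list", length(cols))
  k <- 0L
  for (j in seq_len(ncol(cm$counts))) {
    lib <- cm$samples$library_id[j]
    src <- cm$counts[, j]
    for (b in seq_len(B)) {
      k <- k + 1L
      cols[[k]] <- if (fraction == 1) src else
        with_rng_seed(derive_seed(seed, lib, b),
                      stats::rbinom(n, size = src, prob = fraction))
      meta[[k]] <- data.frame(library_id = lib,
                              arm = cm$samples$arm[j],
                              pseudo_rep = b,
                              stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- rownames(cm$counts)
  count_matrix(counts, do.call(rbind, meta))
}
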