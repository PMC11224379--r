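#' Planted truth for a RIP-seq enrichment simulation
#'
#' @param bound_intron_keys character vector of intron keys carrying planted
#'   IP enrichment (must be a subset of the atlas when simulated against one).
#' @param planted_fold IP-over-control mean fold on bound introns (>= 1).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2); 0 gives
#'   Poisson counts.
#' @param depth expected reads per control library.
#' @return a \code{rip_truth} list.
#' @export
rip_truth <- function(bound_intron_keys, planted_fold = 8, dispersion = 0.05,
                      depth = 1e5) {
  stopifnot(planted_fold >= 1, dispersion >= 0, depth > 0)
  structure(list(bound_intron_keys = unique(as.character(bound_intron_keys)),
                 planted_fold = planted_fold, dispersion = dispersion,
                 depth = depth),
            class = "rip_truth")
}

#' Simulate IP and control RIP-seq counts over an intron atlas
#'
#' Per-intron base means are log-normal(meanlog = log 50, sdlog = 1) across
#' introns, rescaled so a control library's expected column sum equals
#' \code{truth$depth}. Counts are negative-binomial with common dispersion
#' \code{truth$dispersion}. IP means are the control means multiplied by
#' \code{truth$planted_fold} on bound introns only, so the raw IP:control
#' count ratio on a bound intron converges to the planted fold with depth; an
#' IP column's expected sum therefore exceeds \code{depth} by the planted
#' enrichment mass (the bound fraction is small in realistic settings and the
#' excess is absorbed by median-of-ratios normalization downstream).
#'
#' @param atlas an \code{intron_atlas} (non-empty).
#' @param truth a \code{rip_truth}; bound keys must exist in the atlas.
#' @param n_libraries libraries per arm.
#' @param seed integer seed; identical inputs give identical counts.
#' @return a \code{count_matrix} with arms "IP" and "control" and the truth
#'   attached as attribute \code{"truth"}.
#' @export
simulate_rip_counts <- function(atlas, truth, n_libraries = 1, seed) {
  stopifnot(inherits(atlas, "intron_atlas"), inherits(truth, "rip_truth"))
  introns <- atlas_introns(atlas)
  if (nrow(introns) == 0L) stop("empty atlas: nothing to simulate")
  if (!all(truth$bound_intron_keys %in% introns$intron_key)) {
    stop("bound_intron_keys must be a subset of the atlas introns")
  }
  n_libraries <- as.integer(n_libraries)
  stopifnot(n_libraries >= 1L)

  with_rng_seed(seed, {
    n <- nrow(introns)
    base <- stats::rlnorm(n, meanlog = log(50), sdlog = 1)
    mu_ct <- base * truth$depth / sum(base)
    bound <- introns$intron_key %in% truth$bound_intron_keys
    mu_ip <- mu_ct * ifelse(bound, truth$planted_fold, 1)
    size <- if (truth$dispersion == 0) Inf else 1 / truth$dispersion

    draw <- function(mu) {
      if (is.infinite(size)) stats::rpois(n, mu) else
        stats::rnbinom(n, mu = mu, size = size)
    }
    libs <- c(paste0("IP", seq_len(n_libraries)),
              paste0("C", seq_len(n_libraries)))
    arms <- rep(c("IP", "control"), each = n_libraries)
    counts <- sapply(seq_along(libs), function(j) {
      draw(if (arms[j] == "IP") mu_ip else mu_ct)
    })
    rownames(counts) <- introns$intron_key
    colnames(counts) <- libs
    cm <- count_matrix(counts, data.frame(library_id = libs, arm = arms,
                                          stringsAsFactors = FALSE))
    attr(cm, "truth") <- truth
    cm
  })
}

#' Simulate control and knockdown exon counts with a planted usage shift
#'
#' Each gene's total count per sample is negative-binomial with mean
#' \code{depth} and dispersion \code{dispersion}, and the total is split
#' multinomially across the gene's exon bins — so replicate-level expression
#' noise is shared by all exons of a gene and cancels out of relative usage,
#' as it does when reads are apportioned within a locus. The control split
#' weight of exon e is a log-normal(log 50, 1) draw times the number of
#' retained transcripts containing e (equal-mix transcript abundance). In the
#' knockdown the weight of every regulated exon is multiplied by
#' \code{1 - usage_shift} before renormalization; a regulated exon's expected
#' usage is therefore \code{p (1 - shift) / (1 - shift * p_reg)} where
#' \code{p_reg} is the gene's total regulated weight — the nominal factor up
#' to the small renormalization term.
#'
#' @param catalog a filtered \code{transcript_catalog}.
#' @param truth an \code{annotation_truth} from \code{simulate_annotation};
#'   its planted alternative exons are the default regulated set.
#' @param usage_shift planted relative decrease of regulated-exon usage in the
#'   knockdown, in [0, 1).
#' @param n_reps replicates per condition (>= 1).
#' @param dispersion NB dispersion alpha.
#' @param depth expected counts per gene per sample.
#' @param seed integer seed.
#' @param regulated_exons optional character vector of exon keys to regulate;
#'   defaults to every planted alternative exon in \code{truth}.
#' @return list with \code{counts} (a \code{count_matrix}, arms "control" and
#'   "knockdown"), \code{gene_index} (exon_key -> gene_id data.frame) and
#'   \code{regulated_exons}.
#' @export
simulate_exon_counts <- function(catalog, truth, usage_shift, n_reps = 3,
                                 dispersion = 0.05, depth = 1e5, seed,
                                 regulated_exons = NULL) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (!is.numeric(usage_shift) || usage_shift < 0 || usage_shift >= 1) {
    stop("`usage_shift` must lie in [0, 1)")
  }
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L, dispersion >= 0, depth > 0)
  ex <- catalog$exons
  if (nrow(ex) == 0L) stop("empty catalog: nothing to simulate")
  if (is.null(regulated_exons)) {
    stopifnot(inherits(truth, "annotation_truth"))
    regulated_exons <- truth$alt_exons$exon_key
  }

  key <- exon_key(ex$chrom, ex$start, ex$end)
  ntx_in <- tapply(ex$transcript_id, paste(ex$gene_id, key),
                   function(t) length(unique(t)))
  u <- !duplicated(paste(ex$gene_id, key))
  gene_index <- data.frame(exon_key = key[u], gene_id = ex$gene_id[u],
                           stringsAsFactors = FALSE)
  gene_index$n_tx <- as.integer(ntx_in[paste(gene_index$gene_id,
                                             gene_index$exon_key)])

  with_rng_seed(seed, {
    w <- stats::rlnorm(nrow(gene_index), log(50), 1) * gene_index$n_tx
    reg <- gene_index$exon_key %in% regulated_exons
    w_kd <- w * ifelse(reg, 1 - usage_shift, 1)
    size <- if (dispersion == 0) Inf else 1 / dispersion
    gene_of <- gene_index$gene_id
    gene_ids <- unique(gene_of)
    libs <- c(paste0("ctrl", seq_len(n_reps)), paste0("kd", seq_len(n_reps)))
    arms <- rep(c("control", "knockdown"), each = n_reps)
    counts <- matrix(0L, nrow(gene_index), length(libs))
    for (j in seq_along(libs)) {
      ww <- if (arms[j] == "control") w else w_kd
      for (g in gene_ids) {
        i <- which(gene_of == g)
        tot <- if (is.infinite(size)) stats::rpois(1L, depth) else
          stats::rnbinom(1L, mu = depth, size = size)
        counts[i, j] <- stats::rmultinom(1L, tot, ww[i])[, 1L]
      }
    }
    rownames(counts) <- gene_index$exon_key
    colnames(counts) <- libs
    cm <- count_matrix(counts, data.frame(library_id = libs, arm = arms,
                                          stringsAsFactors = FALSE))
    list(counts = cm,
         gene_index = gene_index[, c("exon_key", "gene_id")],
         regulated_exons = gene_index$exon_key[reg])
  })
}
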