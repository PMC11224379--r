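#' Count read intervals over atlas introns
#'
#' Counts, per library, how many read intervals overlap each unique atlas
#' intron by at least 1 bp. A read overlapping several introns increments all
#' of them (union counting). Reads on chromosomes absent from the atlas are
#' tallied as unassigned and reported with a warning.
#'
#' @param atlas an \code{intron_atlas}.
#' @param reads a named list, one element per library, each a data.frame with
#'   columns (chrom, start, end) in 0-based half-open coordinates (BED
#'   convention) or a \code{GRanges}.
#' @param arms character vector parallel to \code{reads} giving each
#'   library's arm ("IP" or "control").
#' @return a \code{count_matrix} over the unique atlas introns.
#' @export
count_overlaps <- function(atlas, reads, arms) {
  stopifnot(inherits(atlas, "intron_atlas"), is.list(reads),
            length(arms) == length(reads))
  if (is.null(names(reads))) names(reads) <- paste0("lib", seq_along(reads))
  introns <- atlas_introns(atlas)
  if (nrow(introns) == 0L) stop("empty atlas: nothing to count over")
  atlas_gr <- GenomicRanges::GRanges(
    introns$chrom,
    IRanges::IRanges(introns$start + 1L, introns$end)
  )
  counts <- matrix(0L, nrow(introns), length(reads),
                   dimnames = list(introns$intron_key, names(reads)))
  for (j in seq_along(reads)) {
    r <- reads[[j]]
    if (!methods::is(r, "GRanges")) {
      stopifnot(all(c("chrom", "start", "end") %in% names(r)))
      r <- GenomicRanges::GRanges(r$chrom,
                                  IRanges::IRanges(r$start + 1L, r$end))
    }
    off_chrom <- !(as.character(GenomicRanges::seqnames(r)) %in%
                     unique(introns$chrom))
    if (any(off_chrom)) {
      warning(sum(off_chrom), " read(s) in library ", names(reads)[j],
              " on chromosomes absent from the atlas; counted as unassigned")
    }
    # off-atlas chromosomes are reported above; silence the redundant
    # seqlevel mismatch warning from the overlap engine
    counts[, j] <- suppressWarnings(
      GenomicRanges::countOverlaps(atlas_gr, r, minoverlap = 1L))
    message("library ", names(reads)[j], ": ", length(r), " reads, ",
            sum(counts[, j]), " intron-overlap events")
  }
  count_matrix(counts, data.frame(library_id = names(reads), arm = arms,
                                  stringsAsFactors = FALSE))
}

#' Median-of-ratios size factors
#'
#' The DESeq-style normalization constant: for each sample, the median over
#' features of the ratio of its count to the feature's geometric mean across
#' samples. Only features with a nonzero count in every sample enter the
#' median.
#'
#' @param counts a numeric matrix or a \code{count_matrix}.
#' @return named vector of strictly positive per-sample factors. A single
#'   sample gets factor 1.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) {
    return(stats::setNames(1, colnames(counts)))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no feature has nonzero counts in all samples; ",
         "add a pseudocount or aggregate features before normalizing")
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  stats::setNames(sf, colnames(counts))
}

#' Simplified negative-binomial Wald test for IP-over-control enrichment
#'
#' A deliberately transparent stand-in for a full NB GLM analysis: per intron,
#' the normalized-count mean is fitted independently in each arm, a single
#' per-intron NB dispersion (variance = mu + alpha * mu^2) is estimated by
#' method of moments from the replicate spread, pooled across arms and floored
#' at 1e-8, and a Wald statistic is formed on the log2 fold change with a
#' delta-method standard error. Two-sided normal p-values are
#' Benjamini-Hochberg adjusted across all tested introns.
#'
#' The reported \code{log2_fold_change} adds a pseudocount of 0.5 to each
#' arm's mean so it stays finite for display and thresholding; the test
#' statistic itself uses the raw means. Introns with zero counts in both arms
#' get p = 1 and log2 fold change 0; when exactly one arm is all-zero its
#' mean is floored, for the statistic only, at the smallest observable
#' normalized mean (0.5 / (n_arm * mean size factor)) — a boundary rule, not
#' a pseudocount policy.
#'
#' @param cm a \code{count_matrix} with >= 2 (pseudo-)replicate columns per
#'   arm; arms must be exactly \code{ip_arm} and \code{control_arm}.
#' @param size_factors optional per-sample factors; estimated by
#'   \code{estimate_size_factors} when NULL.
#' @param ip_arm,control_arm arm labels (defaults "IP", "control").
#' @return an \code{enrichment_table} data.frame: intron_key, base_mean,
#'   log2_fold_change, se, stat, wald_p, bh_q.
#' @export
test_enrichment <- function(cm, size_factors = NULL,
                            ip_arm = "IP", control_arm = "control") {
  stopifnot(inherits(cm, "count_matrix"))
  arms <- cm$samples$arm
  for (a in c(ip_arm, control_arm)) {
    if (sum(arms == a) < 2L) {
      stop("arm '", a, "' needs >= 2 (pseudo-)replicate columns; ",
           "run subsample_pseudoreplicates first")
    }
  }
  K <- cm$counts
  if (is.null(size_factors)) size_factors <- estimate_size_factors(K)
  Y <- sweep(K, 2, size_factors, "/")

  fit_arm <- function(label) {
    j <- which(arms == label)
    list(q = rowMeans(Y[, j, drop = FALSE]),
         v = row_var(Y[, j, drop = FALSE]),
         n = length(j),
         inv_sf = mean(1 / size_factors[j]),
         mean_sf = mean(size_factors[j]))
  }
  ip <- fit_arm(ip_arm)
  ct <- fit_arm(control_arm)

  # method-of-moments dispersion, pooled across arms, floored
  mom <- function(a) (a$v - a$q * a$inv_sf) / a$q^2
  w_ip <- ip$n - 1L
  w_ct <- ct$n - 1L
  alpha <- (w_ip * mom(ip) + w_ct * mom(ct)) / (w_ip + w_ct)
  alpha[!is.finite(alpha) | alpha < 1e-8] <- 1e-8

  q_ip <- ip$q
  q_ct <- ct$q
  both_zero <- q_ip == 0 & q_ct == 0
  equal <- q_ip == q_ct
  # one-arm-zero boundary floor (statistic only)
  floor_ip <- 0.5 / (ip$n * ip$mean_sf)
  floor_ct <- 0.5 / (ct$n * ct$mean_sf)
  q_ip_t <- ifelse(q_ip == 0, floor_ip, q_ip)
  q_ct_t <- ifelse(q_ct == 0, floor_ct, q_ct)

  var_q <- function(q, a) (q * a$inv_sf + alpha * q^2) / a$n
  se_log2 <- sqrt(var_q(q_ip_t, ip) / q_ip_t^2 +
                    var_q(q_ct_t, ct) / q_ct_t^2) / log(2)
  lfc_stat <- log2(q_ip_t / q_ct_t)
  stat <- ifelse(equal, 0, lfc_stat / se_log2)
  p <- 2 * stats::pnorm(-abs(stat))
  p[both_zero] <- 1

  lfc_disp <- log2((q_ip + 0.5) / (q_ct + 0.5))
  lfc_disp[both_zero] <- 0

  out <- data.frame(
    intron_key = rownames(K),
    base_mean = rowMeans(Y),
    log2_fold_change = lfc_disp,
    se = se_log2,
    stat = stat,
    wald_p = p,
    bh_q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"))
}

#' Call bound introns by fold-change and FDR thresholds
#'
#' Strict inequalities on both criteria: an intron is called when its fold
#' change exceeds \code{min_fold} (i.e. \code{2^log2_fold_change > min_fold})
#' and its BH q-value is below \code{max_fdr}.
#'
#' @param table an \code{enrichment_table}.
#' @param min_fold fold-change threshold (default 3).
#' @param max_fdr FDR threshold (default 0.05).
#' @return character vector of called intron keys.
#' @export
call_bound <- function(table, min_fold = 3, max_fdr = 0.05) {
  stopifnot(inherits(table, "enrichment_table"))
  if (nrow(table) == 0L) return(character(0))
  hit <- 2^table$log2_fold_change > min_fold & table$bh_q < max_fdr
  table$intron_key[hit & !is.na(hit)]
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("enrichment_table:", nrow(x), "introns;",
      sum(x$bh_q < 0.05, na.rm = TRUE), "at q < 0.05\n")
  NextMethod()
}
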