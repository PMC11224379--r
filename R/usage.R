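#' Per-sample relative exon usage
#'
#' Usage of exon e in sample s is its count divided by the total count of its
#' gene in that sample (sum over the gene's exon bins). Genes with a zero
#' total in some sample have undefined usage there; those (gene, sample)
#' pairs are flagged and the usage set to NA.
#'
#' @param cm a \code{count_matrix} of exon counts.
#' @param gene_index data.frame mapping \code{exon_key} to \code{gene_id};
#'   every counted exon must be mapped.
#' @return data.frame (exon_key, gene_id, then one usage column per sample),
#'   with flagged (gene_id, library_id) pairs in attribute \code{"flagged"}.
#' @export
usage_proportions <- function(cm, gene_index) {
  stopifnot(inherits(cm, "count_matrix"))
  K <- cm$counts
  idx <- match(rownames(K), gene_index$exon_key)
  if (anyNA(idx)) {
    stop("exon(s) missing from gene_index: ",
         paste(utils::head(rownames(K)[is.na(idx)], 5), collapse = ", "))
  }
  gene <- gene_index$gene_id[idx]
  tot <- rowsum(K, gene)                       # gene x sample totals
  gt <- tot[match(gene, rownames(tot)), , drop = FALSE]
  usage <- K / gt
  usage[gt == 0] <- NA_real_
  flagged <- which(tot == 0, arr.ind = TRUE)
  flagged <- data.frame(gene_id = rownames(tot)[flagged[, 1L]],
                        library_id = colnames(tot)[flagged[, 2L]],
                        stringsAsFactors = FALSE)
  out <- data.frame(exon_key = rownames(K), gene_id = gene,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(usage))
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}

#' Overdispersed two-proportion test for differential exon usage
#'
#' For each exon the test compares exon-versus-rest-of-gene counts between
#' conditions with a quasi-binomial score statistic: condition-level usage
#' proportions are estimated from pooled counts, and the binomial score
#' variance is inflated by a dispersion factor estimated from the
#' replicate-to-replicate Pearson spread (floored at 1). When a condition has
#' fewer than two replicate columns it is expanded into bootstrap
#' pseudo-replicates first (binomial thinning, as in the RIP stage), which is
#' where the replicate spread then comes from. Exons of genes with a zero
#' total in any sample are excluded from testing (NA statistics). Two-sided
#' normal p-values are BH-adjusted across all tested exons.
#'
#' @param ctrl,kd \code{count_matrix} objects for the two conditions over the
#'   same exon set.
#' @param gene_index exon_key -> gene_id map covering all exons.
#' @param B,fraction,seed pseudo-replicate parameters used only when a
#'   condition has a single column.
#' @return a \code{usage_table} data.frame: exon_key, gene_id, usage_ctrl,
#'   usage_kd (condition-level usage proportions), log2_usage_ratio (log2 of
#'   the exon-versus-rest relative usage ratio, knockdown over control — for
#'   small usage values this approximates the plain proportion ratio but is
#'   unaffected by the gene-total change a perturbed exon itself induces),
#'   stat, p, bh_q.
#' @export
test_differential_usage <- function(ctrl, kd, gene_index, B = 3,
                                    fraction = 0.8, seed = 1) {
  stopifnot(inherits(ctrl, "count_matrix"), inherits(kd, "count_matrix"))
  if (!setequal(rownames(ctrl$counts), rownames(kd$counts))) {
    miss <- c(setdiff(rownames(ctrl$counts), rownames(kd$counts)),
              setdiff(rownames(kd$counts), rownames(ctrl$counts)))
    stop("exon(s) absent from one condition's matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  if (ncol(ctrl$counts) < 2L) {
    ctrl <- subsample_pseudoreplicates(ctrl, fraction, B, seed)
  }
  if (ncol(kd$counts) < 2L) {
    kd <- subsample_pseudoreplicates(kd, fraction, B, derive_seed(seed, "kd"))
  }
  Kc <- ctrl$counts
  Kk <- kd$counts[rownames(Kc), , drop = FALSE]
  idx <- match(rownames(Kc), gene_index$exon_key)
  if (anyNA(idx)) {
    stop("exon(s) missing from gene_index: ",
         paste(utils::head(rownames(Kc)[is.na(idx)], 5), collapse = ", "))
  }
  gene <- gene_index$gene_id[idx]

  tot_c <- rowsum(Kc, gene)
  tot_k <- rowsum(Kk, gene)
  gt_c <- tot_c[match(gene, rownames(tot_c)), , drop = FALSE]
  gt_k <- tot_k[match(gene, rownames(tot_k)), , drop = FALSE]
  testable <- rowSums(gt_c == 0) == 0 & rowSums(gt_k == 0) == 0

  Xc <- rowSums(Kc); Nc <- rowSums(gt_c)
  Xk <- rowSums(Kk); Nk <- rowSums(gt_k)
  p_c <- Xc / Nc
  p_k <- Xk / Nk
  p0 <- (Xc + Xk) / (Nc + Nk)
  # exon-vs-rest relative usage: the estimand of the score test, and exactly
  # the planted factor when one exon of a gene is perturbed (the plain
  # proportion ratio also absorbs the induced change of the gene total)
  ratio <- (p_k / (1 - p_k)) / (p_c / (1 - p_c))

  # Pearson replicate dispersion, pooled over both conditions, floored at 1
  disp_part <- function(K, gt, p_cond) {
    mu <- gt * p_cond
    v <- gt * p_cond * (1 - p_cond)
    r <- (K - mu)^2 / v
    r[v == 0] <- NA
    list(ss = rowSums(r, na.rm = TRUE), m = rowSums(!is.na(r)))
  }
  dc <- disp_part(Kc, gt_c, p_c)
  dk <- disp_part(Kk, gt_k, p_k)
  df_phi <- dc$m + dk$m - 2
  phi <- ifelse(df_phi > 0, (dc$ss + dk$ss) / df_phi, 1)
  phi <- pmax(phi, 1)

  v0 <- phi * p0 * (1 - p0) * (1 / Nc + 1 / Nk)
  stat <- ifelse(p_c == p_k, 0, (p_k - p_c) / sqrt(v0))
  stat[!testable] <- NA
  p <- 2 * stats::pnorm(-abs(stat))
  p[!is.na(stat) & stat == 0] <- 1

  out <- data.frame(
    exon_key = rownames(Kc),
    gene_id = gene,
    usage_ctrl = p_c,
    usage_kd = p_k,
    log2_usage_ratio = log2(ratio),
    stat = stat,
    p = p,
    bh_q = NA_real_,
    stringsAsFactors = FALSE
  )
  out$bh_q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  rownames(out) <- NULL
  structure(out, class = c("usage_table", "data.frame"))
}

#' Call differentially used exons
#'
#' @param table a \code{usage_table}.
#' @param max_fdr strict FDR threshold (exons with \code{bh_q < max_fdr}).
#' @return character vector of called exon keys.
#' @export
call_differential <- function(table, max_fdr = 0.05) {
  stopifnot(inherits(table, "usage_table"))
  if (nrow(table) == 0L) return(character(0))
  hit <- !is.na(table$bh_q) & table$bh_q < max_fdr
  table$exon_key[hit]
}

#' @export
print.usage_table <- function(x, ...) {
  cat("usage_table:", nrow(x), "exons;",
      sum(x$bh_q < 0.05, na.rm = TRUE), "at q < 0.05\n")
  NextMethod()
}
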