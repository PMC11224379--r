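#' Simulate a multi-isoform transcript annotation with planted splicing truth
#'
#' Generates a syntactically valid GTF (exon features only, 1-based inclusive
#' coordinates), a CCDS-style transcript-ID whitelist, and a ground-truth
#' record of every planted alternative exon together with the introns that
#' flank it. The gene complement is a mixture of five structure classes:
#' \describe{
#'   \item{single}{one transcript; removed downstream by the
#'     two-or-more-transcripts filter.}
#'   \item{cassette}{two transcripts differing by one skipped internal exon;
#'     plants the cassette exon, its two immediate flanking introns and the
#'     skipping intron of the excluding transcript.}
#'   \item{terminal}{two transcripts sharing a common 5' block and diverging
#'     into mutually exclusive terminal structures (a miniature of the
#'     GLS KGA/GAC arrangement).}
#'   \item{tss_only}{two transcripts identical except for the 5' boundary of
#'     the first exon; removed downstream by the TSS-only filter.}
#'   \item{non_ccds}{a cassette-like gene whose second transcript is withheld
#'     from the CCDS list; removed downstream by the CCDS filter.}
#' }
#' Setting \code{gls_like = TRUE} makes the first gene a full 19-exon GLS-like
#' gene: transcript A carries exons 1-15 (the GAC-like isoform, exon 15
#' exclusive and terminal) and transcript B carries exons 1-14 plus 16-19 (the
#' KGA-like isoform). The intron between exons 14 and 15 — "intron 14" — is
#' then planted as the upstream flank of alternative exon 15.
#'
#' Genes are laid out 50 per chromosome with 1 kb inter-gene gaps. The
#' generator is a pure function of its parameters and \code{seed}.
#'
#' @param n_genes number of genes to simulate (>= 1).
#' @param props named proportions over the five structure classes
#'   \code{c(single, cassette, terminal, tss_only, non_ccds)}; must be
#'   non-negative and sum to 1.
#' @param gls_like if TRUE, gene 1 is the fixed 19-exon GLS-like gene.
#' @param seed integer RNG seed; identical inputs give byte-identical output.
#' @return a list with elements \code{gtf} (character vector of GTF lines),
#'   \code{ccds_ids} (character vector of whitelisted transcript IDs) and
#'   \code{truth}, an object of class \code{annotation_truth} holding
#'   \code{genes} (per-gene class and expected retention), \code{alt_exons},
#'   \code{flanking_introns} (gene, exon key, intron key, side), and the
#'   planted \code{tss_only_gene_ids} / \code{non_ccds_transcript_ids}.
#' @export
simulate_annotation <- function(n_genes,
                                props = c(single = 0.2, cassette = 0.35,
                                          terminal = 0.15, tss_only = 0.15,
                                          non_ccds = 0.15),
                                gls_like = FALSE,
                                seed) {
  stopifnot(is.numeric(n_genes), n_genes >= 1)
  classes <- c("single", "cassette", "terminal", "tss_only", "non_ccds")
  if (is.null(names(props)) || !all(names(props) %in% classes)) {
    stop("`props` must be named with a subset of: ",
         paste(classes, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(classes)), classes)
  full[names(props)] <- props
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8) {
    stop("structure-mix proportions must be non-negative and sum to 1 (got ",
         sum(full), ")")
  }
  n_genes <- as.integer(n_genes)

  with_rng_seed(seed, {
    gene_class <- sample(classes, n_genes, replace = TRUE, prob = full)
    if (gls_like) gene_class[1L] <- "gls_like"

    genes_per_chrom <- 50L
    gap <- 1000L

    gtf <- character(0)
    ccds <- character(0)
    gene_rows <- vector("list", n_genes)
    alt_rows <- vector("list", n_genes)
    intron_rows <- vector("list", n_genes)
    tss_only_ids <- character(0)
    non_ccds_tx <- character(0)

    cursor <- 1000L
    chrom_i <- 1L
    for (g in seq_len(n_genes)) {
      if (g > 1L && (g - 1L) %% genes_per_chrom == 0L) {
        chrom_i <- chrom_i + 1L
        cursor <- 1000L
      }
      chrom <- paste0("chr", chrom_i)
      gid <- sprintf("g%04d", g)
      strand <- sample(c("+", "-"), 1L)
      cls <- gene_class[g]

      built <- .build_gene(gid, cls, chrom, strand, cursor)
      cursor <- built$next_cursor + gap
      gtf <- c(gtf, built$gtf)
      ccds <- c(ccds, built$ccds)
      non_ccds_tx <- c(non_ccds_tx, built$non_ccds)
      if (cls == "tss_only") tss_only_ids <- c(tss_only_ids, gid)
      gene_rows[[g]] <- data.frame(
        gene_id = gid, class = cls, chrom = chrom, strand = strand,
        retained = cls %in% c("cassette", "terminal", "gls_like"),
        stringsAsFactors = FALSE
      )
      alt_rows[[g]] <- built$alt_exons
      intron_rows[[g]] <- built$introns
    }

    truth <- structure(
      list(
        genes = do.call(rbind, gene_rows),
        alt_exons = .rbind_or_empty(alt_rows,
          c("gene_id", "exon_key")),
        flanking_introns = .rbind_or_empty(intron_rows,
          c("gene_id", "exon_key", "intron_key", "side")),
        tss_only_gene_ids = tss_only_ids,
        non_ccds_transcript_ids = non_ccds_tx
      ),
      class = "annotation_truth"
    )
    list(gtf = gtf, ccds_ids = ccds, truth = truth)
  })
}

.rbind_or_empty <- function(rows, cols) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Build one gene. Exon slots are laid out genomically ascending; the
# transcription index of genomic slot i is i on "+" and K+1-i on "-", so minus
# strand genes are genomic mirrors of the same transcription-order structure.
.build_gene <- function(gid, cls, chrom, strand, cursor) {
  if (cls == "gls_like") {
    k <- 19L
    shared_m <- 14L
    a_extra <- 1L
    b_extra <- 4L
  } else if (cls == "terminal") {
    shared_m <- sample(3:6, 1L)
    a_extra <- 1L
    b_extra <- sample(1:3, 1L)
    k <- shared_m + a_extra + b_extra
  } else if (cls == "single") {
    k <- sample(4:8, 1L)
  } else {
    k <- sample(4:8, 1L)  # cassette, tss_only, non_ccds
  }

  exon_len <- sample(80:300, k, replace = TRUE)
  intron_len <- if (k > 1L) sample(200:1500, k - 1L, replace = TRUE) else integer(0)
  start0 <- integer(k)
  end0 <- integer(k)
  pos <- cursor
  for (i in seq_len(k)) {
    start0[i] <- pos
    end0[i] <- pos + exon_len[i]
    pos <- end0[i] + if (i < k) intron_len[i] else 0L
  }
  # genomic slot of transcription index t
  slot <- function(t) if (strand == "+") t else k + 1L - t
  # genomic gap interval between two transcription-adjacent indices
  gap_iv <- function(ta, tb) {
    p <- sort(c(slot(ta), slot(tb)))
    c(end0[p[1L]], start0[p[2L]])
  }
  up_down <- function(genomic_left) {
    # side of a flanking intron relative to its exon, in transcription
    # orientation: the genomically-left flank is upstream on "+", downstream
    # on "-".
    if (genomic_left) {
      if (strand == "+") "upstream" else "downstream"
    } else {
      if (strand == "+") "downstream" else "upstream"
    }
  }

  alt_exons <- NULL
  introns <- NULL
  tx <- list()          # transcript_id -> transcription indices
  ccds <- character(0)
  non_ccds <- character(0)
  shift1 <- NULL        # tss_only: shifted copy of first exon

  if (cls == "single") {
    tx[[paste0(gid, ".t1")]] <- seq_len(k)
    ccds <- paste0(gid, ".t1")
  } else if (cls %in% c("cassette", "non_ccds")) {
    s <- sample(2:(k - 1L), 1L)   # skipped transcription index
    tx[[paste0(gid, ".t1")]] <- seq_len(k)
    tx[[paste0(gid, ".t2")]] <- setdiff(seq_len(k), s)
    if (cls == "cassette") {
      ccds <- paste0(gid, c(".t1", ".t2"))
      ek <- exon_key(chrom, start0[slot(s)], end0[slot(s)])
      lf <- gap_iv(s - 1L, s)
      rf <- gap_iv(s, s + 1L)
      sk <- gap_iv(s - 1L, s + 1L)
      left_is_upstream <- slot(s - 1L) < slot(s)
      alt_exons <- data.frame(gene_id = gid, exon_key = ek,
                              stringsAsFactors = FALSE)
      introns <- data.frame(
        gene_id = gid,
        exon_key = ek,
        intron_key = c(intron_key(chrom, lf[1], lf[2], strand),
                       intron_key(chrom, rf[1], rf[2], strand),
                       intron_key(chrom, sk[1], sk[2], strand)),
        side = c(up_down(slot(s - 1L) < slot(s)),
                 up_down(slot(s + 1L) < slot(s)),
                 "spanning"),
        stringsAsFactors = FALSE
      )
    } else {
      ccds <- paste0(gid, ".t1")
      non_ccds <- paste0(gid, ".t2")
    }
  } else if (cls %in% c("terminal", "gls_like")) {
    m <- shared_m
    a_idx <- m + 1L                      # A-exclusive terminal exon
    b_idx <- (m + 2L):k                  # B-exclusive tail
    tx[[paste0(gid, ".t1")]] <- c(seq_len(m), a_idx)
    tx[[paste0(gid, ".t2")]] <- c(seq_len(m), b_idx)
    ccds <- paste0(gid, c(".t1", ".t2"))

    ekey <- function(t) exon_key(chrom, start0[slot(t)], end0[slot(t)])
    ik <- function(iv) intron_key(chrom, iv[1], iv[2], strand)

    rows <- list()
    # A-exclusive exon: upstream flank (m, m+1) in A; spanning intron
    # (m, m+2) contributed by B, which skips it.
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, exon_key = ekey(a_idx),
      intron_key = ik(gap_iv(m, a_idx)),
      side = up_down(slot(m) < slot(a_idx)), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, exon_key = ekey(a_idx),
      intron_key = ik(gap_iv(m, m + 2L)),
      side = "spanning", stringsAsFactors = FALSE)
    # B-exclusive exons: immediate flanks within B only (A never spans them).
    b_path <- c(m, b_idx)                # transcription adjacencies in B
    for (j in seq_along(b_idx)) {
      t <- b_idx[j]
      prev_t <- b_path[j]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, exon_key = ekey(t),
        intron_key = ik(gap_iv(prev_t, t)),
        side = up_down(slot(prev_t) < slot(t)), stringsAsFactors = FALSE)
      if (t < k) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, exon_key = ekey(t),
          intron_key = ik(gap_iv(t, t + 1L)),
          side = up_down(slot(t + 1L) < slot(t)), stringsAsFactors = FALSE)
      }
    }
    alt_exons <- data.frame(
      gene_id = gid,
      exon_key = vapply(c(a_idx, b_idx), ekey, character(1)),
      stringsAsFactors = FALSE
    )
    introns <- do.call(rbind, rows)
  } else if (cls == "tss_only") {
    tx[[paste0(gid, ".t1")]] <- seq_len(k)
    tx[[paste0(gid, ".t2")]] <- seq_len(k)
    ccds <- paste0(gid, c(".t1", ".t2"))
    delta <- sample(20:50, 1L)
    first_slot <- slot(1L)
    shift1 <- c(first_slot, delta)
  }

  # Emit GTF exon lines (1-based inclusive), exon_number in transcription order.
  lines <- character(0)
  for (tid in names(tx)) {
    tr_idx <- tx[[tid]]
    for (j in seq_along(tr_idx)) {
      t <- tr_idx[j]
      p <- slot(t)
      s0 <- start0[p]
      e0 <- end0[p]
      if (cls == "tss_only" && tid == paste0(gid, ".t2") && t == 1L) {
        if (strand == "+") s0 <- s0 + shift1[2L] else e0 <- e0 - shift1[2L]
      }
      lines <- c(lines, sprintf(
        "%s\trbpsplice_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; exon_number \"%d\";",
        chrom, s0 + 1L, e0, strand, gid, tid, j))
    }
  }

  list(gtf = lines, ccds = ccds, non_ccds = non_ccds,
       alt_exons = alt_exons, introns = introns,
       next_cursor = max(end0))
}

#' @export
print.annotation_truth <- function(x, ...) {
  cat("annotation_truth:", nrow(x$genes), "genes;",
      nrow(x$alt_exons), "planted alternative exons;",
      length(unique(x$flanking_introns$intron_key)), "planted introns\n")
  print(table(x$genes$class))
  invisible(x)
}
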