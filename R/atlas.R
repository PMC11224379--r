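#' Parse exon features from a GTF file into a transcript catalog
#'
#' Reads a GTF annotation (via \code{rtracklayer}) and keeps exon features
#' only. GTF 1-based inclusive coordinates are converted to the 0-based
#' half-open convention used throughout the package. Transcripts with a single
#' exon are retained; all transcripts of a gene must share one chromosome and
#' strand (trans-spliced / multi-chromosome genes are rejected).
#'
#' @param gtf path to a GTF file, or a character vector of GTF lines.
#' @return a \code{transcript_catalog}: a list with element \code{exons}, a
#'   data.frame of (gene_id, transcript_id, chrom, start, end, strand) sorted
#'   by genomic start within transcript, and a print method.
#' @export
parse_gtf <- function(gtf) {
  if (length(gtf) != 1L || !file.exists(gtf)) {
    path <- tempfile(fileext = ".gtf")
    on.exit(unlink(path), add = TRUE)
    writeLines(gtf, path)
  } else {
    path <- gtf
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) GenomicRanges::GRanges()
  )
  if (length(gr) == 0L) return(.new_catalog(.empty_exon_df()))
  md <- S4Vectors::mcols(gr)
  keep <- !is.na(md$type) & md$type == "exon"
  gr <- gr[keep]
  if (length(gr) == 0L) return(.new_catalog(.empty_exon_df()))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id)) {
    stop("GTF exon features must carry gene_id and transcript_id attributes")
  }
  ex <- data.frame(
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ex <- ex[order(ex$gene_id, ex$transcript_id, ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  .validate_exons(ex)
  .new_catalog(ex)
}

.empty_exon_df <- function() {
  data.frame(gene_id = character(0), transcript_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

.new_catalog <- function(exons) {
  structure(list(exons = exons), class = "transcript_catalog")
}

.validate_exons <- function(ex) {
  for (tid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tid, , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop("malformed input: overlapping exons within transcript ", tid)
    }
  }
  per_gene <- unique(ex[, c("gene_id", "chrom", "strand")])
  dup <- per_gene$gene_id[duplicated(per_gene$gene_id)]
  if (length(dup) > 0L) {
    stop("gene(s) spanning multiple chromosomes/strands are not supported: ",
         paste(unique(dup), collapse = ", "))
  }
  invisible(ex)
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat("transcript_catalog:",
      length(unique(x$exons$gene_id)), "genes,",
      length(unique(x$exons$transcript_id)), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Apply the CCDS / multi-isoform / TSS-only transcript filters
#'
#' Reduces a catalog to the gene set on which alternative-exon detection is
#' meaningful, applying exactly, and in this order:
#' \enumerate{
#'   \item drop transcripts absent from the CCDS whitelist (version suffixes
#'     of the form \code{.N} are stripped from both sides before matching);
#'   \item drop genes left with fewer than two transcripts;
#'   \item drop genes whose remaining transcripts differ only at the 5'
#'     boundary of the first exon (identical internal splice junctions and
#'     identical 3' terminal boundary) — transcripts varying only by
#'     transcriptional start site carry no usable splicing signal.
#' }
#' The operation is idempotent and may legitimately empty the catalog.
#'
#' @param catalog a \code{transcript_catalog}.
#' @param ccds_ids character vector of CCDS-supported transcript IDs.
#' @return the filtered \code{transcript_catalog}.
#' @export
apply_transcript_filters <- function(catalog, ccds_ids) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  ex <- catalog$exons
  if (nrow(ex) == 0L) return(catalog)
  strip <- function(x) sub("\\.[0-9]+$", "", x)
  keep_tx <- strip(ex$transcript_id) %in% strip(ccds_ids)
  ex <- ex[keep_tx, , drop = FALSE]

  if (nrow(ex) > 0L) {
    ntx <- tapply(ex$transcript_id, ex$gene_id,
                  function(t) length(unique(t)))
    keep_genes <- names(ntx)[ntx >= 2L]
    ex <- ex[ex$gene_id %in% keep_genes, , drop = FALSE]
  }

  if (nrow(ex) > 0L) {
    drop_genes <- character(0)
    for (gid in unique(ex$gene_id)) {
      e <- ex[ex$gene_id == gid, , drop = FALSE]
      sigs <- vapply(split(e, e$transcript_id), .tx_signature_minus_tss,
                     character(1))
      if (length(unique(sigs)) == 1L) drop_genes <- c(drop_genes, gid)
    }
    ex <- ex[!(ex$gene_id %in% drop_genes), , drop = FALSE]
  }
  rownames(ex) <- NULL
  .new_catalog(ex)
}

# All exon boundaries of a transcript except the 5' boundary of its first exon
# (in transcription orientation), serialized for comparison.
.tx_signature_minus_tss <- function(e) {
  e <- e[order(e$start), , drop = FALSE]
  b <- as.vector(rbind(e$start, e$end))   # start1,end1,start2,end2,...
  if (e$strand[1L] == "+") b <- b[-1L] else b <- b[-length(b)]
  paste(b, collapse = ",")
}

#' Classify exons as constitutive or alternative
#'
#' An exon (identified by its exact genomic key chrom:start-end) is
#' constitutive when it occurs in every retained transcript of its gene and
#' alternative otherwise. Exact-coordinate identity means alternative 5'/3'
#' splice-site variants of overlapping exons register as distinct, hence
#' alternative.
#'
#' @param catalog a filtered \code{transcript_catalog}.
#' @return an \code{exon_status}: data.frame (gene_id, exon_key, chrom, start,
#'   end, status) with status in \{constitutive, alternative\}.
#' @export
classify_exons <- function(catalog) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  ex <- catalog$exons
  out <- list()
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    n_tx <- length(unique(e$transcript_id))
    key <- exon_key(e$chrom, e$start, e$end)
    occ <- tapply(e$transcript_id, key, function(t) length(unique(t)))
    u <- !duplicated(key)
    ku <- key[u]
    out[[gid]] <- data.frame(
      gene_id = gid,
      exon_key = ku,
      chrom = e$chrom[u],
      start = e$start[u],
      end = e$end[u],
      strand = e$strand[u],
      status = ifelse(occ[ku] == n_tx, "constitutive", "alternative"),
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), exon_key = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), status = character(0))
  rownames(res) <- NULL
  structure(res, class = c("exon_status", "data.frame"))
}

#' Build the atlas of introns around alternative exons
#'
#' For every alternative exon the atlas records, per transcript containing it,
#' the immediate upstream and downstream flanking introns (strand-aware
#' transcription orientation), and, per transcript skipping it, the single
#' intron spanning the exon locus between that transcript's neighboring exons
#' (side \code{"spanning"}). Introns are deduplicated by exact key
#' (chrom:start-end:strand); a deduplicated intron keeps every
#' (exon, side) link that produced it. Zero-length gaps between adjacent
#' exons are skipped with a warning.
#'
#' @param catalog the filtered \code{transcript_catalog}.
#' @param status the \code{exon_status} computed from the same catalog.
#' @param flanks_only if TRUE, omit spanning (skipping) introns and keep
#'   immediate flanks only.
#' @return an \code{intron_atlas}: data.frame with one row per
#'   (intron, exon, side) link and columns (intron_key, chrom, start, end,
#'   strand, gene_id, exon_key, side).
#' @export
build_intron_atlas <- function(catalog, status, flanks_only = FALSE) {
  stopifnot(inherits(catalog, "transcript_catalog"),
            inherits(status, "exon_status"))
  ex <- catalog$exons
  alt <- status[status$status == "alternative", , drop = FALSE]
  rows <- list()
  skipped_zero <- 0L
  for (gid in unique(alt$gene_id)) {
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    strand <- e$strand[1L]
    chrom <- e$chrom[1L]
    a <- alt[alt$gene_id == gid, , drop = FALSE]
    tx_split <- split(e, e$transcript_id)
    for (i in seq_len(nrow(a))) {
      ek <- a$exon_key[i]
      es <- a$start[i]
      ee <- a$end[i]
      for (tr in tx_split) {
        tr <- tr[order(tr$start), , drop = FALSE]
        hit <- which(tr$start == es & tr$end == ee)
        if (length(hit) == 1L) {
          j <- hit
          if (j > 1L) {
            iv <- c(tr$end[j - 1L], tr$start[j])
            side <- if (strand == "+") "upstream" else "downstream"
            if (iv[2L] > iv[1L]) {
              rows[[length(rows) + 1L]] <- c(chrom, iv, strand, gid, ek, side)
            } else skipped_zero <- skipped_zero + 1L
          }
          if (j < nrow(tr)) {
            iv <- c(tr$end[j], tr$start[j + 1L])
            side <- if (strand == "+") "downstream" else "upstream"
            if (iv[2L] > iv[1L]) {
              rows[[length(rows) + 1L]] <- c(chrom, iv, strand, gid, ek, side)
            } else skipped_zero <- skipped_zero + 1L
          }
        } else if (!flanks_only && nrow(tr) > 1L) {
          j <- which(tr$end[-nrow(tr)] <= es & tr$start[-1L] >= ee)
          if (length(j) == 1L) {
            iv <- c(tr$end[j], tr$start[j + 1L])
            if (iv[2L] > iv[1L]) {
              rows[[length(rows) + 1L]] <-
                c(chrom, iv, strand, gid, ek, "spanning")
            } else skipped_zero <- skipped_zero + 1L
          }
        }
      }
    }
  }
  if (skipped_zero > 0L) {
    warning(skipped_zero,
            " zero-length intron(s) between adjacent exons were skipped")
  }
  if (length(rows) == 0L) {
    out <- data.frame(intron_key = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), gene_id = character(0),
                      exon_key = character(0), side = character(0),
                      stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, rows)
    out <- data.frame(
      intron_key = intron_key(m[, 1L], as.integer(m[, 2L]),
                              as.integer(m[, 3L]), m[, 4L]),
      chrom = m[, 1L], start = as.integer(m[, 2L]),
      end = as.integer(m[, 3L]), strand = m[, 4L],
      gene_id = m[, 5L], exon_key = m[, 6L], side = m[, 7L],
      stringsAsFactors = FALSE
    )
    out <- unique(out)
    out <- out[order(out$chrom, out$start, out$end, out$exon_key, out$side), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("intron_atlas", "data.frame"))
}

#' Unique intron intervals of an atlas
#'
#' @param atlas an \code{intron_atlas}.
#' @return data.frame of deduplicated (intron_key, chrom, start, end, strand,
#'   gene_id) rows.
#' @export
atlas_introns <- function(atlas) {
  stopifnot(inherits(atlas, "intron_atlas"))
  u <- unique(as.data.frame(atlas)[, c("intron_key", "chrom", "start", "end",
                                       "strand", "gene_id")])
  rownames(u) <- NULL
  u
}

#' Export an intron atlas as BED6 text
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged. One line per (intron, exon, side) link, name field
#' \code{gene_id|exon_key|side}, score 0, strand populated, sorted by
#' (chrom, start, end, name) so identical atlases export identical bytes.
#'
#' @param atlas an \code{intron_atlas}.
#' @param path optional output file; when NULL the lines are returned.
#' @return character vector of BED lines (invisibly when \code{path} given).
#' @export
export_atlas <- function(atlas, path = NULL) {
  stopifnot(inherits(atlas, "intron_atlas"))
  df <- as.data.frame(atlas)
  if (nrow(df) == 0L) {
    lines <- character(0)
  } else {
    name <- paste(df$gene_id, df$exon_key, df$side, sep = "|")
    ord <- order(df$chrom, df$start, df$end, name)
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     df$chrom[ord], df$start[ord], df$end[ord],
                     name[ord], df$strand[ord])
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.intron_atlas <- function(x, ...) {
  cat("intron_atlas:", length(unique(x$intron_key)), "introns,",
      length(unique(x$exon_key)), "alternative exons,",
      length(unique(x$gene_id)), "genes\n")
  invisible(x)
}
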