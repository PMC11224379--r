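# Plain-text readers/writers for the pipeline's exchange formats.

#' Write / read a counts TSV (feature_id, one column per sample)
#'
#' The sample metadata travels in a sidecar JSON written next to the TSV
#' (same path with extension .samples.json) so a counts file round-trips to a
#' \code{count_matrix}.
#'
#' @param cm a \code{count_matrix}.
#' @param path output TSV path.
#' @export
write_counts_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cm$samples, paste0(path, ".samples.json"),
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param path TSV path written by \code{write_counts_tsv}.
#' @return a \code{count_matrix}.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df[[1L]]
  samples <- jsonlite::read_json(paste0(path, ".samples.json"),
                                 simplifyVector = TRUE)
  count_matrix(counts, as.data.frame(samples))
}

#' Write / read a survival cohort TSV (sample_id, expression, time, event)
#'
#' @param cohort a \code{survival_cohort} data.frame.
#' @param path TSV path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(
    as.data.frame(cohort)[, c("sample_id", "expression", "time", "event")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("sample_id", "expression", "time", "event") %in% names(df)))
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0/1")
  if (any(df$time <= 0)) stop("times must be positive")
  class(df) <- c("survival_cohort", "data.frame")
  df
}

#' Write / read a MID TSV (metabolite, mass_shift, replicate, fraction)
#'
#' @param mid data.frame as produced by \code{simulate_mid}.
#' @param path TSV path.
#' @export
write_mid_tsv <- function(mid, path) {
  utils::write.table(mid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mid_tsv
#' @export
read_mid_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' Serialize a planted-truth object as JSON
#'
#' Truth tables are written separately from the data payloads they describe
#' (no truth leaks into GTF/TSV files).
#'
#' @param truth any truth object (annotation_truth, rip_truth, ...).
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "rows",
                       auto_unbox = TRUE)
  invisible(path)
}
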