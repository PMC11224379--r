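#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (via \code{survival::survfit}): S(0) = 1, a
#' right-continuous downward step at each event time, censoring reducing the
#' risk set without a step.
#'
#' @param cohort a \code{survival_cohort} or any data.frame with \code{time}
#'   and \code{event} columns.
#' @return a \code{km_curve} data.frame: time, n_risk, n_event, n_censor,
#'   surv.
#' @export
km_curve <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(cohort))
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  structure(out, class = c("km_curve", "data.frame"))
}

#' @export
plot.km_curve <- function(x, ..., xlab = "time", ylab = "survival") {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), main = "", ...)
  invisible(x)
}

# Core vectorized log-rank machinery. `z` is an n x K 0/1 matrix of group-A
# membership indicators (one column per grouping to test). Returns per-column
# U (observed minus expected events in group A), V (sum of hypergeometric
# variances), chi2 and p. Ties are handled by processing all events at a time
# in one risk-set step.
.logrank_stats <- function(time, event, z) {
  o <- order(time, decreasing = TRUE)
  tt <- time[o]
  ev <- event[o]
  Z <- z[o, , drop = FALSE]
  storage.mode(Z) <- "double"
  CZ <- apply(Z, 2, cumsum)                       # n x K
  if (is.null(dim(CZ))) CZ <- matrix(CZ, nrow = 1L)
  r <- rle(tt)
  block_end <- cumsum(r$lengths)
  block_id <- rep(seq_along(r$lengths), r$lengths)
  d <- rowsum(ev, block_id)[, 1L]                  # events per distinct time
  keep <- d > 0
  if (!any(keep)) {
    k <- ncol(z)
    return(list(U = numeric(k), V = numeric(k), chi2 = numeric(k),
                p = rep(1, k)))
  }
  n_risk <- block_end[keep]
  dk <- d[keep]
  N1 <- CZ[block_end[keep], , drop = FALSE]        # group-A at risk
  O1 <- rowsum(Z * ev, block_id)[keep, , drop = FALSE]
  frac <- N1 / n_risk
  U <- colSums(O1 - dk * frac)
  V <- colSums(dk * frac * (1 - frac) * (n_risk - dk) / pmax(n_risk - 1, 1))
  chi2 <- ifelse(V > 0, U^2 / V, 0)
  p <- ifelse(V > 0, stats::pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  list(U = U, V = V, chi2 = chi2, p = p)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank test: summed observed-minus-
#' expected events in group A over the distinct event times, divided by the
#' summed hypergeometric variances. When no comparable events exist (V = 0)
#' the statistic is 0 and p = 1.
#'
#' @param group_a,group_b data.frames with \code{time} and \code{event}
#'   columns; both non-empty.
#' @return list(chi2, p).
#' @export
logrank <- function(group_a, group_b) {
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  z <- matrix(rep(c(1, 0), c(nrow(group_a), nrow(group_b))), ncol = 1L)
  s <- .logrank_stats(time, event, z)
  list(chi2 = s$chi2[1L], p = s$p[1L])
}

#' Exhaustive minimum-p log-rank cutpoint scan
#'
#' Evaluates every admissible dichotomization of the cohort by expression:
#' candidate cuts are the midpoints between consecutive sorted unique
#' expression values (a cut can never split tied values), cuts leaving a
#' group smaller than \code{ceiling(min_group_frac * n)} are skipped, and the
#' cut with the smallest log-rank p is reported (ties broken toward the lower
#' cut). The returned minimum p is NOT adjusted for the multiplicity of the
#' scan and is anti-conservative as a test of association; see
#' \code{\link{permutation_adjust}}.
#'
#' @param cohort a \code{survival_cohort}-like data.frame with columns
#'   expression, time, event; at least 20 samples.
#' @param min_group_frac minimum group size as a fraction of n, in
#'   [0, 0.5); 0 restores the literal all-possible-cutoffs scan.
#' @return a \code{cutpoint_result}: list(best_cut, min_p, best_chi2, scan
#'   (data.frame cut, chi2, p, n_low, n_high), n, min_group_frac,
#'   adjusted_p = NULL).
#' @export
scan_cutpoints <- function(cohort, min_group_frac = 0.1) {
  cohort <- as.data.frame(cohort)
  n <- nrow(cohort)
  if (n < 20L) stop("cutpoint scan requires a cohort of at least 20 samples")
  if (min_group_frac < 0 || min_group_frac >= 0.5) {
    stop("`min_group_frac` must lie in [0, 0.5)")
  }
  s <- .scan_core(cohort$time, cohort$event, cohort$expression,
                  min_group_frac)
  if (is.null(s)) stop("no admissible cut under the minimum-group constraint")
  best <- which(s$p == min(s$p))[1L]               # ties -> lower cut
  structure(list(best_cut = s$cuts[best], min_p = s$p[best],
                 best_chi2 = s$chi2[best],
                 scan = data.frame(cut = s$cuts, chi2 = s$chi2, p = s$p,
                                   n_low = s$n_low, n_high = s$n_high),
                 n = n, min_group_frac = min_group_frac,
                 adjusted_p = NULL),
            class = "cutpoint_result")
}

.scan_core <- function(time, event, expression, min_group_frac) {
  n <- length(time)
  ux <- sort(unique(expression))
  if (length(ux) < 2L) return(NULL)
  cuts <- (ux[-length(ux)] + ux[-1L]) / 2
  n_high <- vapply(cuts, function(cc) sum(expression > cc), integer(1))
  n_low <- n - n_high
  min_size <- max(ceiling(min_group_frac * n), 1L)
  ok <- n_high >= min_size & n_low >= min_size
  if (!any(ok)) return(NULL)
  cuts <- cuts[ok]
  n_high <- n_high[ok]
  n_low <- n_low[ok]
  z <- outer(expression, cuts, ">") * 1
  st <- .logrank_stats(time, event, z)
  list(cuts = cuts, chi2 = st$chi2, p = st$p, n_low = n_low, n_high = n_high)
}

#' Permutation adjustment of the minimum-p cutpoint scan
#'
#' Re-runs the full cutpoint scan on cohorts whose expression values are
#' randomly permuted against (time, event), and reports
#' \code{(1 + #\{min_p* <= min_p\}) / (n_perm + 1)} — an exact permutation
#' p-value for the selection-inflated minimum-p statistic.
#'
#' @param cohort the cohort the result was computed on.
#' @param result a \code{cutpoint_result} from \code{scan_cutpoints}.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return the \code{cutpoint_result} with \code{adjusted_p} (and
#'   \code{n_perm}) filled in.
#' @export
permutation_adjust <- function(cohort, result, n_perm, seed) {
  stopifnot(inherits(result, "cutpoint_result"))
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  cohort <- as.data.frame(cohort)
  n_perm <- as.integer(n_perm)
  hits <- with_rng_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      xp <- sample(cohort$expression)
      s <- .scan_core(cohort$time, cohort$event, xp, result$min_group_frac)
      if (!is.null(s) && min(s$p) <= result$min_p) h <- h + 1L
    }
    h
  })
  result$adjusted_p <- (1 + hits) / (n_perm + 1)
  result$n_perm <- n_perm
  result
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("cutpoint_result: n =", x$n, "| best cut =", signif(x$best_cut, 4),
      "| min log-rank p =", format.pval(x$min_p), "\n")
  cat("  scan:", nrow(x$scan), "admissible cuts (min group frac",
      x$min_group_frac, ")\n")
  if (!is.null(x$adjusted_p)) {
    cat("  permutation-adjusted p =", format.pval(x$adjusted_p),
        "(", x$n_perm, "permutations )\n")
  }
  invisible(x)
}
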