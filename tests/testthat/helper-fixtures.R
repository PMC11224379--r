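# Fixtures and independent brute-force oracles used across the suite.

# A bare intron atlas with n disjoint introns on one chromosome; enough for
# count-level stages that do not need a full annotation.
make_test_atlas <- function(n) {
  start <- as.integer(seq(0, by = 2000, length.out = n))
  df <- data.frame(
    intron_key = sprintf("chr1:%d-%d:+", start, start + 500L),
    chrom = "chr1", start = start, end = start + 500L, strand = "+",
    gene_id = sprintf("g%05d", seq_len(n)),
    exon_key = sprintf("chr1:%d-%d", start + 600L, start + 700L),
    side = "upstream", stringsAsFactors = FALSE
  )
  structure(df, class = c("intron_atlas", "data.frame"))
}

# Subset a count_matrix to one arm.
arm_matrix <- function(cm, arm) {
  j <- cm$samples$arm == arm
  count_matrix(cm$counts[, j, drop = FALSE], cm$samples[j, , drop = FALSE])
}

# Run the full usage test on a simulate_exon_counts result.
usage_test_from_sim <- function(ec) {
  test_differential_usage(arm_matrix(ec$counts, "control"),
                          arm_matrix(ec$counts, "knockdown"),
                          ec$gene_index)
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j>=i} m p_(j) / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(pmin(m * p[o][i:m] / (i:m), 1))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force log-rank: explicit per-event-time O/E/V tabulation, written
# independently of the package's vectorized machinery.
logrank_bruteforce <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  ga <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  U <- 0
  V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & ga)
    d <- sum(event == 1 & time == t)
    o1 <- sum(event == 1 & time == t & ga)
    U <- U + o1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) U^2 / V else 0
  p <- if (V > 0) pchisq(chi2, 1, lower.tail = FALSE) else 1
  list(chi2 = chi2, p = p)
}

# Exhaustive hypergeometric tail: enumerate all C(universe, k) draws.
hyper_bruteforce <- function(n_universe, n_marked, k_draw, min_overlap) {
  draws <- utils::combn(n_universe, k_draw)
  marked <- seq_len(n_marked)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= min_overlap)
}

# Explicit Welch t with Welch-Satterthwaite df.
welch_bruteforce <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

gls_gtf_path <- function() {
  system.file("extdata", "gls_like.gtf", package = "rbpsplice")
}

gls_ccds_path <- function() {
  system.file("extdata", "gls_like_ccds.txt", package = "rbpsplice")
}
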