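test_that("read overlap counting follows the >= 1 bp union rule", {
  atl <- make_test_atlas(2)   # introns [0,500) and [2000,2500)
  reads <- list(l1 = data.frame(chrom = "chr1",
                                start = c(150, 495, 600),
                                end = c(160, 505, 610)))
  suppressMessages(cm <- count_overlaps(atl, reads, arms = "IP"))
  expect_equal(unname(cm$counts[, 1]), c(2L, 0L))
  # a read spanning two adjacent introns increments both
  atl2 <- atl
  atl2$start <- c(0L, 500L)
  atl2$end <- c(500L, 1000L)
  atl2$intron_key <- sprintf("chr1:%d-%d:+", atl2$start, atl2$end)
  reads2 <- list(l1 = data.frame(chrom = "chr1", start = 490, end = 510))
  suppressMessages(cm2 <- count_overlaps(atl2, reads2, arms = "IP"))
  expect_equal(unname(cm2$counts[, 1]), c(1L, 1L))
  # empty read set -> all-zero column
  suppressWarnings(suppressMessages(cm3 <- count_overlaps(
    atl, list(l1 = data.frame(chrom = character(0), start = integer(0),
                              end = integer(0))), arms = "IP")))
  expect_true(all(cm3$counts == 0))
  # off-atlas chromosomes warn and stay unassigned
  expect_warning(
    suppressMessages(count_overlaps(
      atl, list(l1 = data.frame(chrom = "chrX", start = 1, end = 10)),
      arms = "IP")),
    "unassigned")
})

test_that("median-of-ratios size factors match the hand computation", {
  m <- matrix(c(2, 8, 4, 16), 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical columns -> all factors 1
  m2 <- matrix(c(3, 7, 3, 7, 3, 7), 2,
               dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  expect_equal(unname(estimate_size_factors(m2)), c(1, 1, 1))
  # single sample -> 1
  expect_equal(unname(estimate_size_factors(m[, 1, drop = FALSE])), 1)
  # no feature nonzero everywhere -> informative error
  m3 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("f1", "f2"), NULL))
  expect_error(estimate_size_factors(m3), "pseudocount")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(1)
  m <- matrix(rpois(600, 80), 150,
              dimnames = list(sprintf("f%d", 1:150), sprintf("s%d", 1:4)))
  m[, 3] <- m[, 3] * 3L
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("identical IP and control columns give the exact null", {
  set.seed(3)
  m <- matrix(rpois(400, 60), 100)
  rownames(m) <- sprintf("i%d", 1:100)
  counts <- cbind(m, m)
  cm <- count_matrix(counts, data.frame(
    library_id = sprintf("l%d", 1:8),
    arm = rep(c("IP", "control"), each = 4)))
  tab <- test_enrichment(cm)
  expect_true(all(tab$log2_fold_change == 0))
  expect_true(all(tab$wald_p == 1))
  expect_true(all(tab$bh_q >= tab$wald_p - 1e-15))
})

test_that("swapping arm labels negates the fold change and keeps p", {
  atl <- make_test_atlas(200)
  bound <- atlas_introns(atl)$intron_key[1:10]
  cm <- simulate_rip_counts(atl, rip_truth(bound, 4, 0.05, 5e4),
                            n_libraries = 2, seed = 8)
  ps <- subsample_pseudoreplicates(cm, 0.8, 3, seed = 9)
  tab <- test_enrichment(ps)
  swapped <- ps
  swapped$samples$arm <- ifelse(ps$samples$arm == "IP", "control", "IP")
  tab_s <- test_enrichment(swapped)
  expect_equal(tab_s$log2_fold_change, -tab$log2_fold_change,
               tolerance = 1e-12)
  expect_equal(tab_s$wald_p, tab$wald_p, tolerance = 1e-12)
})

test_that("a missing arm or missing replicates is an error", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), NULL))
  cm <- count_matrix(m, data.frame(library_id = c("l1", "l2"),
                                   arm = c("IP", "IP")))
  expect_error(test_enrichment(cm), "control")
})

test_that("rescaling one library leaves normalized fold changes invariant", {
  # noiseless proportional columns: count_ij = f_i * s_j exactly
  f <- c(20, 50, 125, 300)
  s <- c(1, 2, 1, 3, 2, 1, 4, 1)
  counts <- outer(f, s)
  rownames(counts) <- sprintf("i%d", seq_along(f))
  samples <- data.frame(library_id = sprintf("l%d", 1:8),
                        arm = rep(c("IP", "control"), each = 4))
  tab1 <- test_enrichment(count_matrix(counts, samples))
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * 5
  sf1 <- estimate_size_factors(counts)
  sf2 <- estimate_size_factors(counts2)
  # size factors are defined up to a common constant: the rescaled library's
  # factor moves by exactly c relative to every other library
  expect_equal(unname(sf2[1] / sf2[2]), 5 * unname(sf1[1] / sf1[2]),
               tolerance = 1e-12)
  tab2 <- test_enrichment(count_matrix(counts2, samples))
  expect_equal(tab2$log2_fold_change, tab1$log2_fold_change,
               tolerance = 1e-12)
  expect_equal(tab2$wald_p, tab1$wald_p, tolerance = 1e-12)
})

test_that("bound-intron calling applies strict fold and FDR thresholds", {
  tab <- structure(data.frame(
    intron_key = c("a", "b", "c", "d"),
    base_mean = 10,
    log2_fold_change = c(log2(3), 3, 3, 1),
    se = 1, stat = 1,
    wald_p = c(0.001, 0.01, 0.2, 0.001),
    bh_q = c(0.01, 0.04, 0.5, 0.01)),
    class = c("enrichment_table", "data.frame"))
  expect_equal(call_bound(tab), "b")   # fold exactly 3 ("a") is excluded
  expect_equal(call_bound(tab, min_fold = 1.5), c("a", "b", "d"))
  empty <- structure(tab[0, ], class = c("enrichment_table", "data.frame"))
  expect_equal(call_bound(empty), character(0))
})

test_that("pipeline q-values equal the brute-force BH definition", {
  atl <- make_test_atlas(300)
  cm <- simulate_rip_counts(atl, rip_truth(character(0), 1, 0.05, 3e4),
                            n_libraries = 1, seed = 21)
  ps <- subsample_pseudoreplicates(cm, 0.8, 3, seed = 22)
  tab <- test_enrichment(ps)
  expect_equal(tab$bh_q, bh_bruteforce(tab$wald_p), tolerance = 1e-12)
  # and on plain random p-vectors against p.adjust
  set.seed(9)
  for (m in c(1, 10, 1000)) {
    p <- runif(m)
    expect_equal(p.adjust(p, "BH"), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("empirical IP:control ratio on bound introns approaches the planted fold", {
  atl <- make_test_atlas(500)
  bound <- atlas_introns(atl)$intron_key[1:25]
  cm <- simulate_rip_counts(atl, rip_truth(bound, 8, dispersion = 1e-4,
                                           depth = 2e6),
                            n_libraries = 1, seed = 31)
  i <- rownames(cm$counts) %in% bound
  ratio <- sum(cm$counts[i, cm$samples$arm == "IP"]) /
    sum(cm$counts[i, cm$samples$arm == "control"])
  expect_equal(ratio, 8, tolerance = 0.05)
  # fold = 1 is the null configuration but the truth still records the set
  cm0 <- simulate_rip_counts(atl, rip_truth(bound, 1, 0.05, 1e4),
                             n_libraries = 1, seed = 32)
  expect_setequal(attr(cm0, "truth")$bound_intron_keys, bound)
  # seed contract
  cm1 <- simulate_rip_counts(atl, rip_truth(bound, 8, 0.05, 1e4), 1, seed = 1)
  cm2 <- simulate_rip_counts(atl, rip_truth(bound, 8, 0.05, 1e4), 1, seed = 2)
  expect_false(identical(cm1$counts, cm2$counts))
  expect_identical(attr(cm1, "truth"), attr(cm2, "truth"))
})

test_that("simulating over an empty atlas is an error", {
  empty <- make_test_atlas(1)[0, ]
  class(empty) <- c("intron_atlas", "data.frame")
  expect_error(simulate_rip_counts(empty, rip_truth("x", 2), 1, seed = 1),
               "empty atlas")
})
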