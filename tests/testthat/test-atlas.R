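test_that("GTF coordinates convert to 0-based half-open and non-exon lines are ignored", {
  gtf <- c(
    "chr1\tsrc\tgene\t101\t500\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";"
  )
  cat1 <- parse_gtf(gtf)
  expect_equal(nrow(cat1$exons), 2L)
  expect_equal(cat1$exons$start, c(100L, 300L))
  expect_equal(cat1$exons$end, c(200L, 400L))
})

test_that("empty input yields an empty catalog, not an error", {
  cat1 <- parse_gtf(character(0))
  expect_s3_class(cat1, "transcript_catalog")
  expect_equal(nrow(cat1$exons), 0L)
  expect_equal(nrow(apply_transcript_filters(cat1, "x")$exons), 0L)
})

test_that("overlapping exons within a transcript are a malformed-input error", {
  gtf <- c(
    "chr1\tsrc\texon\t101\t250\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";",
    "chr1\tsrc\texon\t200\t400\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";"
  )
  expect_error(parse_gtf(gtf), "g1\\.t1")
})

make_two_tx_gtf <- function(strand = "+") {
  # 3 exon slots; t1 = all three, t2 skips the middle exon
  c(
    sprintf("chr1\tsrc\texon\t101\t200\t.\t%s\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";", strand),
    sprintf("chr1\tsrc\texon\t301\t400\t.\t%s\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";", strand),
    sprintf("chr1\tsrc\texon\t501\t600\t.\t%s\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";", strand),
    sprintf("chr1\tsrc\texon\t101\t200\t.\t%s\t.\tgene_id \"g1\"; transcript_id \"g1.t2\";", strand),
    sprintf("chr1\tsrc\texon\t501\t600\t.\t%s\t.\tgene_id \"g1\"; transcript_id \"g1.t2\";", strand)
  )
}

test_that("transcript filters apply CCDS, transcript-count and TSS-only rules in order", {
  cat1 <- parse_gtf(make_two_tx_gtf())
  # one transcript lacking CCDS -> gene dropped at the two-transcript step
  flt <- apply_transcript_filters(cat1, "g1.t1")
  expect_equal(nrow(flt$exons), 0L)
  # both CCDS -> cassette gene is a fixed point
  flt2 <- apply_transcript_filters(cat1, c("g1.t1", "g1.t2"))
  expect_identical(flt2$exons, cat1$exons)
  # idempotence
  flt3 <- apply_transcript_filters(flt2, c("g1.t1", "g1.t2"))
  expect_identical(flt3$exons, flt2$exons)
  # version suffixes are stripped before matching
  flt4 <- apply_transcript_filters(cat1, c("g1.t1.3", "g1.t2.12"))
  expect_identical(flt4$exons, cat1$exons)
})

test_that("genes varying only by transcriptional start site are removed", {
  gtf <- c(
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";",
    "chr1\tsrc\texon\t151\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t2\";",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t2\";"
  )
  flt <- apply_transcript_filters(parse_gtf(gtf), c("g1.t1", "g1.t2"))
  expect_equal(nrow(flt$exons), 0L)
  # same on minus strand: the 5' boundary of the first exon is the genomic
  # end of the genomically-last exon
  gtf_m <- c(
    "chr1\tsrc\texon\t101\t200\t.\t-\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";",
    "chr1\tsrc\texon\t301\t400\t.\t-\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";",
    "chr1\tsrc\texon\t101\t200\t.\t-\t.\tgene_id \"g1\"; transcript_id \"g1.t2\";",
    "chr1\tsrc\texon\t301\t380\t.\t-\t.\tgene_id \"g1\"; transcript_id \"g1.t2\";"
  )
  flt_m <- apply_transcript_filters(parse_gtf(gtf_m), c("g1.t1", "g1.t2"))
  expect_equal(nrow(flt_m$exons), 0L)
})

test_that("exon classification is exact-coordinate membership across transcripts", {
  cat1 <- parse_gtf(make_two_tx_gtf())
  st <- classify_exons(cat1)
  expect_equal(st$status[st$exon_key == "chr1:300-400"], "alternative")
  expect_equal(sum(st$status == "constitutive"), 2L)
  # two transcripts sharing no exon -> everything alternative
  gtf2 <- c(
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t1\";",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id \"g1\"; transcript_id \"g1.t2\";"
  )
  st2 <- classify_exons(parse_gtf(gtf2))
  expect_true(all(st2$status == "alternative"))
  # single-transcript gene: vacuously constitutive
  st3 <- classify_exons(parse_gtf(make_two_tx_gtf()[1:3]))
  expect_true(all(st3$status == "constitutive"))
})

test_that("a cassette exon yields exactly its two flanks plus the skipping intron", {
  # DERIVED oracle: in the 3-exon/2-transcript toy, enumerate adjacent exon
  # pairs by hand: t1 gives [200,300) and [400,500); t2 gives [200,500).
  cat1 <- parse_gtf(make_two_tx_gtf())
  atl <- build_intron_atlas(cat1, classify_exons(cat1))
  expect_setequal(unique(atl$intron_key),
                  c("chr1:200-300:+", "chr1:400-500:+", "chr1:200-500:+"))
  expect_equal(atl$side[atl$intron_key == "chr1:200-300:+"], "upstream")
  expect_equal(atl$side[atl$intron_key == "chr1:400-500:+"], "downstream")
  expect_equal(atl$side[atl$intron_key == "chr1:200-500:+"], "spanning")
  # flanks-only mode drops the spanning intron
  atl_f <- build_intron_atlas(cat1, classify_exons(cat1), flanks_only = TRUE)
  expect_setequal(unique(atl_f$intron_key),
                  c("chr1:200-300:+", "chr1:400-500:+"))
})

test_that("a catalog with only constitutive exons yields an empty atlas", {
  gtf <- c(make_two_tx_gtf()[1:3],
           sub("g1.t1", "g1.t2", make_two_tx_gtf()[1:3], fixed = TRUE))
  cat1 <- parse_gtf(gtf)
  atl <- build_intron_atlas(cat1, classify_exons(cat1))
  expect_equal(nrow(atl), 0L)
})

test_that("strand reversal mirrors the atlas and swaps upstream/downstream", {
  plus <- parse_gtf(make_two_tx_gtf("+"))
  minus <- parse_gtf(make_two_tx_gtf("-"))
  ap <- build_intron_atlas(plus, classify_exons(plus))
  am <- build_intron_atlas(minus, classify_exons(minus))
  expect_equal(sub(":\\+$", "", unique(ap$intron_key)),
               sub(":-$", "", unique(am$intron_key)))
  swap <- c(upstream = "downstream", downstream = "upstream",
            spanning = "spanning")
  key_p <- paste(sub(":\\+$", "", ap$intron_key), ap$exon_key, ap$side)
  key_m <- paste(sub(":-$", "", am$intron_key), am$exon_key,
                 unname(swap[am$side]))
  expect_setequal(key_p, key_m)
})

test_that("every atlas intron is disjoint from the alternative exon it flanks", {
  sim <- simulate_annotation(80, gls_like = TRUE, seed = 13)
  cat1 <- apply_transcript_filters(parse_gtf(sim$gtf), sim$ccds_ids)
  atl <- build_intron_atlas(cat1, classify_exons(cat1))
  ex <- rbpsplice:::parse_region_key(atl$exon_key)
  flanks <- atl$side != "spanning"
  overlap <- pmax(0, pmin(atl$end, ex$end) - pmax(atl$start, ex$start))
  expect_true(all(overlap[flanks] == 0))
})

test_that("atlas recovers the planted truth exactly over seeds and gene mixes", {
  for (s in c(2, 19)) {
    sim <- simulate_annotation(60, gls_like = TRUE, seed = s)
    flt <- apply_transcript_filters(parse_gtf(sim$gtf), sim$ccds_ids)
    expect_setequal(unique(flt$exons$gene_id),
                    sim$truth$genes$gene_id[sim$truth$genes$retained])
    st <- classify_exons(flt)
    expect_setequal(st$exon_key[st$status == "alternative"],
                    sim$truth$alt_exons$exon_key)
    atl <- build_intron_atlas(flt, st)
    expect_setequal(unique(atl$intron_key),
                    unique(sim$truth$flanking_introns$intron_key))
    got <- paste(atl$intron_key, atl$exon_key, atl$side)
    want <- with(sim$truth$flanking_introns,
                 paste(intron_key, exon_key, side))
    expect_setequal(got, want)
  }
})

test_that("BED export is deterministic, 0-based half-open, and empty for empty atlases", {
  cat1 <- parse_gtf(make_two_tx_gtf())
  atl <- build_intron_atlas(cat1, classify_exons(cat1))
  bed <- export_atlas(atl)
  expect_identical(bed, export_atlas(atl))
  f <- strsplit(bed[1], "\t")[[1]]
  expect_equal(f[c(1, 2, 3, 5, 6)], c("chr1", "200", "300", "0", "+"))
  expect_match(f[4], "^g1\\|chr1:300-400\\|")
  empty <- build_intron_atlas(cat1, structure(
    classify_exons(cat1)[0, ], class = c("exon_status", "data.frame")))
  expect_identical(export_atlas(empty), character(0))
})

test_that("the packaged GLS-like fixture puts intron 14 upstream of alternative exon 15", {
  cat1 <- parse_gtf(gls_gtf_path())
  flt <- apply_transcript_filters(cat1, readLines(gls_ccds_path()))
  st <- classify_exons(flt)
  expect_equal(sum(st$status == "constitutive"), 14L)
  expect_equal(sum(st$status == "alternative"), 5L)
  atl <- build_intron_atlas(flt, st)
  # exon 15 of the GAC-like transcript is chr2:[8000,8200); intron 14 is the
  # gap after exon 14, chr2:[7700,8000)
  hit <- atl[atl$intron_key == "chr2:7700-8000:+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$exon_key, "chr2:8000-8200")
  expect_equal(hit$side, "upstream")
})
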