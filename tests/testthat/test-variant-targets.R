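# SmiRNA enumeration, two-scheme site scoring, consensus prediction and
# target gain/loss.

mk_mature <- function(seq, id = "mirX", locus_id = "locX") {
  data.frame(
    locus_id = locus_id, mature_id = id, offset = 0L, length = nchar(seq),
    seq = seq, stringsAsFactors = FALSE
  )
}

mk_mature_assignment <- function(site, alt, locus_id = "locX",
                                 id = "mirX", pos = 1000L, ref = "A") {
  data.frame(
    locus_id = locus_id, region_label = "mature", offset = site - 1L,
    site = site, mature_id = id, reg_len = 21L, chrom = "chr1", pos = pos,
    ref = ref, alt = alt, ancestral = ref, pop = "cultivated",
    stringsAsFactors = FALSE
  )
}

test_that("one SmiRNA per (mature, SNP, alt allele)", {
  mat <- mk_mature("ACGUACGUACGUACGUACGUA")
  locus <- make_locus(id = "locX")
  a1 <- mk_mature_assignment(site = 3L, alt = "T", ref = "G")
  sm <- enumerate_smirnas(a1, locus, mat)
  expect_identical(nrow(sm), 1L)
  expect_identical(substr(sm$seq, 3, 3), "U")
  expect_identical(sum(seq_chars(sm$seq) != seq_chars(mat$seq)), 1L)
  expect_identical(sm$site, 3L)

  # triallelic SNP expands to two SmiRNAs
  a2 <- mk_mature_assignment(site = 3L, alt = "T,C", ref = "G")
  sm2 <- enumerate_smirnas(a2, locus, mat)
  expect_identical(nrow(sm2), 2L)
  expect_setequal(substr(sm2$seq, 3, 3), c("U", "C"))
})

test_that("minus-strand alleles are complemented into transcript space", {
  mat <- mk_mature("ACGUACGUACGUACGUACGUA")
  locus <- make_locus(id = "locX", strand = "-")
  a <- mk_mature_assignment(site = 5L, alt = "G", ref = "T")
  sm <- enumerate_smirnas(a, locus, mat)
  expect_identical(substr(sm$seq, 5, 5), "C") # genomic G -> transcript C
  # an alt that maps onto the existing transcript base is skipped
  a_same <- mk_mature_assignment(site = 5L, alt = "T", ref = "G")
  expect_identical(nrow(enumerate_smirnas(a_same, locus, mat)), 0L)
})

test_that("site scoring implements both rule sets", {
  mir <- "ACGUACGUACGUACGUACGUA"
  perfect <- revcomp_rna(mir)
  sc <- score_site(mir, perfect)
  expect_identical(sc$score_a, 0)
  expect_true(sc$hit_a && sc$hit_b && sc$consensus)

  # single G:U wobble at miRNA position 5: target base facing position 5
  # is window position L - 5 + 1 = 17; miRNA pos 5 is "A"... choose a G
  # position instead: position 3 is "G", wobble target "U"
  win <- seq_chars(perfect)
  w <- nchar(mir) - 3 + 1
  win[w] <- "U" # G:C -> G:U wobble
  sc2 <- score_site(mir, paste(win, collapse = ""))
  expect_identical(sc2$positions[3], "wobble")
  expect_identical(sc2$score_a, 1.0) # 0.5 doubled inside positions 2-13
  expect_identical(sc2$score_b, 0.5)
  expect_true(sc2$consensus) # one seed defect is allowed under B

  # mismatch at position 10 sinks scheme B regardless of totals
  win10 <- seq_chars(perfect)
  w10 <- nchar(mir) - 10 + 1
  win10[w10] <- "C" # faces A; A:C mismatch
  sc3 <- score_site(mir, paste(win10, collapse = ""))
  expect_identical(sc3$positions[10], "mismatch")
  expect_false(sc3$hit_b)
  expect_true(sc3$hit_a) # weighted penalty 2.0 still under 4
  expect_false(sc3$consensus)

  # position 20 (outside seed and cleavage site) keeps the site
  win20 <- seq_chars(perfect)
  w20 <- nchar(mir) - 20 + 1
  win20[w20] <- "C"
  sc4 <- score_site(mir, paste(win20, collapse = ""))
  expect_true(sc4$consensus)
  expect_identical(sc4$score_a, 1.0) # unweighted outside 2-13
})

test_that("consensus scan equals the brute-force window oracle", {
  cfg <- sim_config(
    seed = 51L, n_chroms = 1L, chrom_len = 40000L, n_loci = 4L,
    n_transcripts = 20L, transcript_len = 200L,
    planted_site_spec = data.frame(
      mirna = c(1L, 2L, 3L, 4L), mismatches = c(0L, 1L, 2L, 0L),
      wobbles = c(0L, 0L, 0L, 2L)
    )
  )
  study <- simulate_study(cfg)
  mirnas <- setNames(study$matures$seq, study$matures$mature_id)
  got <- predict_targets(mirnas, study$transcripts)
  oracle <- brute_force_targets(mirnas, study$transcripts)
  key <- function(d) {
    sort(paste(d$mirna_id, d$transcript_id, d$start, d$score_a, d$score_b))
  }
  expect_identical(key(got), key(oracle))
  # the planted perfect site is among the hits
  ps <- study$truth$planted_sites
  perfect <- ps[ps$mismatches + ps$wobbles == 0L, ]
  for (k in seq_len(nrow(perfect))) {
    expect_true(any(got$mirna_id == perfect$mature_id[k] &
                      got$transcript_id == perfect$transcript[k]))
  }
})

test_that("a heavily mismatched seed is rejected by both routes", {
  mir <- "ACGUACGUACGUACGUACGUA"
  win <- seq_chars(revcomp_rna(mir))
  for (p in 2:7) win[nchar(mir) - p + 1] <- "A" # 6 seed defects vs U/G...
  # force real mismatches: replace with the miRNA base itself (never pairs)
  for (p in 2:7) {
    win[nchar(mir) - p + 1] <- substr(mir, p, p)
  }
  win <- paste(win, collapse = "")
  sc <- score_site(mir, win)
  expect_false(sc$consensus)
  tx <- c(t1 = paste0("AAAAA", rna2dna(win), "AAAAA"))
  expect_identical(nrow(predict_targets(c(mirX = mir), tx)), 0L)
})

test_that("gain/loss sets are disjoint, swap-symmetric and correct", {
  wild <- data.frame(transcript_id = c("t1", "t2", "t3"))
  snp <- data.frame(transcript_id = c("t2", "t4"))
  d <- target_delta(wild, snp)
  expect_identical(d$gained, "t4")
  expect_identical(d$lost, c("t1", "t3"))
  expect_length(intersect(d$gained, d$lost), 0L)
  # swapping roles swaps gained and lost
  d2 <- target_delta(snp, wild)
  expect_identical(d2$gained, d$lost)
  expect_identical(d2$lost, d$gained)
  # identical hit sets
  d3 <- target_delta(wild, wild)
  expect_length(d3$gained, 0L)
  expect_length(d3$lost, 0L)
})

test_that("planted gains and losses are recovered end to end", {
  # wild mature with a perfect site; the SNP at miRNA position 10
  # destroys it under scheme B (lost); a second transcript is perfectly
  # complementary to the SmiRNA only (gained)
  mat <- mk_mature("ACGUACGUACGUACGUACGUA")
  locus <- make_locus(id = "locX")
  a <- mk_mature_assignment(site = 10L, alt = "G", ref = "C")
  sm <- enumerate_smirnas(a, locus, mat)
  expect_identical(substr(sm$seq, 10, 10), "G")
  tx <- c(
    wild_site = paste0("GGGGG", rna2dna(revcomp_rna(mat$seq)), "GGGGG"),
    snp_site = paste0("TTTTT", rna2dna(revcomp_rna(sm$seq)), "TTTTT")
  )
  res <- target_deltas_all(sm, mat, tx)
  expect_identical(res$deltas$n_gained, 1L)
  expect_identical(res$deltas$n_lost, 1L)
  expect_identical(res$deltas$gained, "snp_site")
  expect_identical(res$deltas$lost, "wild_site")
})

test_that("empty transcriptome and length mismatches error", {
  expect_error(predict_targets(c(m = "ACGUACGUACGUACGUACGUA"),
                               character(0)), "empty")
  expect_error(score_site("ACGU", "ACGUA"))
})
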