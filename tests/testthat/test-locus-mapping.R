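# Exact placement, region assignment arithmetic, strand handling and
# conservation classification.

test_that("exact placement finds plus- and minus-strand copies", {
  set.seed(101)
  genome <- c(chr1 = random_dna(10000))
  prec_dna <- substr(genome[["chr1"]], 101, 200)
  hits <- map_precursor_exact(dna2rna(prec_dna), genome)
  expect_identical(hits$start, 100L)
  expect_identical(hits$end, 200L)
  expect_identical(hits$strand, "+")

  rc <- dna2rna(revcomp_dna(substr(genome[["chr1"]], 301, 360)))
  hits2 <- map_precursor_exact(rc, genome)
  expect_true(any(hits2$start == 300L & hits2$strand == "-"))
})

test_that("an absent 80-mer maps nowhere (brute-force cross-check)", {
  set.seed(102)
  genome <- c(chr1 = random_dna(10000))
  repeat {
    probe <- random_dna(80)
    if (!grepl(probe, genome[["chr1"]], fixed = TRUE) &&
          !grepl(revcomp_dna(probe), genome[["chr1"]], fixed = TRUE)) {
      break
    }
  }
  expect_identical(nrow(map_precursor_exact(dna2rna(probe), genome)), 0L)
})

test_that("study precursors map back to their recorded placements", {
  study <- small_study()
  precs <- setNames(study$loci$precursor_seq, study$loci$id)
  mapped <- map_all_precursors(precs, study$genome)
  expect_identical(length(attr(mapped, "unmapped")), 0L)
  key <- function(d) paste(d$id, d$chrom, d$start, d$end, d$strand)
  expect_true(all(key(study$loci) %in% key(mapped)))
})

test_that("plus-strand region assignment gives precursor offsets", {
  locus <- make_locus(start = 1000L, end = 1100L, strand = "+")
  a <- assign_region(locus, make_snp(pos = 1005L))
  expect_identical(a$region_label, "precursor_nonmature")
  expect_identical(a$offset, 5L)
})

test_that("minus-strand offsets count from the transcript 5' end", {
  locus <- make_locus(start = 1000L, end = 1100L, strand = "-",
                      precursor_seq = paste(rep("U", 100), collapse = ""))
  a <- assign_region(locus, make_snp(pos = 1098L, ref = "T", alt = "C"))
  expect_identical(a$region_label, "precursor_nonmature")
  expect_identical(a$offset, 1L) # 1100 - 1 - 1098
})

test_that("matched flanks are labelled with strand-aware up/down", {
  locus <- make_locus(start = 1000L, end = 1100L, strand = "+")
  a <- assign_region(locus, make_snp(pos = 950L))
  expect_identical(a$region_label, "up_flank")
  expect_identical(a$offset, 50L) # flank is [900, 1000)
  # on the minus strand the same genomic position is in the DOWN flank,
  # with the offset measured from the genomic right edge
  locus_m <- make_locus(start = 1000L, end = 1100L, strand = "-")
  am <- assign_region(locus_m, make_snp(pos = 950L))
  expect_identical(am$region_label, "down_flank")
  expect_identical(am$offset, 49L) # 999 - 950
})

test_that("mature label takes precedence and site indices are 1-based", {
  matures <- data.frame(
    locus_id = "mir-1", mature_id = "mir-1-5p", offset = 10L, length = 21L,
    seq = paste(rep("A", 21), collapse = ""), stringsAsFactors = FALSE
  )
  locus <- make_locus(id = "mir-1", start = 1000L, end = 1100L)
  for (case in list(c(pos = 1012L, site = 3L), c(pos = 1010L, site = 1L),
                    c(pos = 1030L, site = 21L))) {
    a <- assign_region(locus, make_snp(pos = case[["pos"]]),
                       matures = matures)
    expect_identical(a$region_label, "mature")
    expect_identical(mature_site_of(a), case[["site"]])
  }
  # one past the mature 3' end is precursor again
  a2 <- assign_region(locus, make_snp(pos = 1031L), matures = matures)
  expect_identical(a2$region_label, "precursor_nonmature")
  expect_identical(a2$offset, 31L)
  expect_error(mature_site_of(a2), "mature")
})

test_that("matched-flank labels partition the overlapping variant set", {
  study <- small_study()
  asn <- assign_regions(study, region_scheme("matched_flank"))
  # each (variant, locus) pair appears exactly once
  expect_false(any(duplicated(paste(asn$chrom, asn$pos, asn$locus_id))))
  # counts conserve: variants inside [start - L, end + L) of some locus
  n_overlap <- 0L
  for (i in seq_len(nrow(study$loci))) {
    lc <- study$loci[i, ]
    L <- lc$end - lc$start
    v <- study$variants
    n_overlap <- n_overlap +
      sum(v$chrom == lc$chrom & v$pos >= lc$start - L & v$pos < lc$end + L)
  }
  expect_identical(nrow(asn), n_overlap)
  expect_true(all(asn$region_label %in%
    c("mature", "precursor_nonmature", "up_flank", "down_flank")))
  expect_true(all(asn$offset >= 0L))
})

test_that("assignments are invariant under a genome strand flip", {
  study <- small_study()
  for (kind in c("matched_flank", "kb_window", "distance_bins")) {
    sch <- region_scheme(kind)
    a1 <- assign_regions(study, sch)
    a2 <- assign_regions(flip_study(study), sch)
    k1 <- sort(paste(a1$locus_id, a1$region_label, a1$offset))
    k2 <- sort(paste(a2$locus_id, a2$region_label, a2$offset))
    expect_identical(k1, k2)
  }
})

test_that("distance bins sit outward from the mature boundaries", {
  matures <- data.frame(
    locus_id = "mir-1", mature_id = "mir-1-5p", offset = 40L, length = 20L,
    seq = paste(rep("A", 20), collapse = ""), stringsAsFactors = FALSE
  )
  locus <- make_locus(id = "mir-1", start = 1000L, end = 1100L)
  sch <- region_scheme("distance_bins", L = 50L, n_bins = 2L)
  # mature spans [1040, 1060); first upstream bin [990, 1040)
  a <- assign_region(locus, make_snp(pos = 1000L), scheme = sch,
                     matures = matures)
  expect_identical(a$region_label, "distance_bin_u1")
  expect_identical(a$offset, 10L)
  a2 <- assign_region(locus, make_snp(pos = 1065L), scheme = sch,
                      matures = matures)
  expect_identical(a2$region_label, "distance_bin_d1")
})

test_that("conservation is exact-match by default and counts recover", {
  expect_true(classify_conserved("ACGUACGUACGUACGUACGUA",
                                 c(x = "ACGUACGUACGUACGUACGUA")))
  expect_false(classify_conserved("ACGUACGUACGUACGUACGUA",
                                  c(x = "ACGUACGUACGUACGUACGUC")))
  expect_true(classify_conserved("ACGUACGUACGUACGUACGUA",
                                 c(x = "ACGUACGUACGUACGUACGUC"),
                                 max_mismatches = 1L))
  # U/T normalization
  expect_true(classify_conserved("ACGU", c(x = "ACGT")))
  expect_error(classify_conserved("ACGU", character(0)), "empty")

  # random queries vs a disjoint random reference: all false, checked
  # against an all-pairs Hamming oracle
  set.seed(7)
  q <- vapply(1:50, function(i) random_rna(21), character(1))
  ref <- setNames(vapply(1:30, function(i) random_rna(21), character(1)),
                  paste0("r", 1:30))
  got <- classify_conserved(q, ref)
  oracle <- vapply(q, function(x) {
    any(vapply(ref, function(y) {
      sum(seq_chars(x) != seq_chars(y)) == 0L
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(got, oracle)
  expect_false(any(got))

  # planted conserved set in the synthetic study is recovered exactly
  study <- small_study()
  flags <- classify_conserved(study$matures$seq,
                              study$truth$conserved_reference)
  by_locus <- vapply(split(flags, study$matures$locus_id), any, logical(1))
  expect_identical(sort(names(by_locus)[by_locus]),
                   study$truth$conserved_ids)
  expect_identical(sum(by_locus), length(study$truth$conserved_ids))
})
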