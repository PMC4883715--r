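# Folding DP vs exhaustive oracle, structure scoring, ddG machinery.

test_that("unpairable sequences fold to the empty structure at 0", {
  m <- default_model()
  f <- fold_mfe("AAAAAAA", m)
  expect_identical(f$structure, ".......")
  expect_identical(f$mfe, 0)
  expect_identical(fold_exhaustive("AAAAAAA", m)$mfe, 0)
})

test_that("a single-helix hairpin scores as stacks plus loop penalty", {
  m <- default_model()
  f <- fold_mfe("GGGGAAAACCCC", m)
  expect_identical(f$structure, "((((....))))")
  # three GC-on-GC stacks (-3.3 each) + tetraloop penalty (5.6)
  expect_equal(f$mfe, 3 * -3.3 + 5.6)
  expect_equal(structure_energy("GGGGAAAACCCC", f$structure, m), f$mfe)
  expect_equal(fold_exhaustive("GGGGAAAACCCC", m)$mfe, f$mfe)
})

test_that("DP fold equals the exhaustive fold on random sequences", {
  m <- default_model()
  set.seed(23)
  for (i in 1:60) {
    s <- random_rna(sample(5:15, 1))
    a <- fold_mfe(s, m)
    b <- fold_exhaustive(s, m)
    expect_identical(a$mfe, b$mfe)
    expect_identical(a$n_pairs, b$n_pairs)
    # the reported structure really has the reported energy
    expect_equal(structure_energy(s, a$structure, m), a$mfe)
    expect_lte(a$mfe, 0)
  }
})

test_that("invalid alphabets and oversized inputs are refused", {
  m <- default_model()
  expect_error(fold_mfe("ACGX", m), "A,C,G,U")
  expect_error(fold_exhaustive(random_rna(19), m), "18")
  expect_identical(fold_mfe("ACGT", m)$seq, "ACGU") # T silently read as U
})

test_that("structure context is stem for paired, loop for unpaired", {
  f <- list(structure = "(((...)))")
  expect_identical(snp_context(f, 0L), "stem")
  expect_identical(snp_context(f, 4L), "loop")
  expect_identical(snp_context(f, c(0L, 4L, 8L)), c("stem", "loop", "stem"))
})

test_that("ddG classification uses the published sign convention", {
  expect_identical(classify_ddg(6.56), "destabilizing")
  expect_identical(classify_ddg(-6.90), "stabilizing")
  expect_identical(classify_ddg(0), "unchanged")
  expect_identical(classify_ddg(c(0.15, -0.25)), c("slight", "slight"))
  expect_identical(classify_ddg(c(0.3, -0.3)),
                   c("destabilizing", "stabilizing"))
  expect_identical(classify_ddg(c(0.05, -0.05)), c("unchanged", "unchanged"))
})

test_that("an alt identical to the transcript base gives ddG = 0 exactly", {
  m <- default_model()
  # minus-strand locus: genomic alt G maps to transcript base C
  prec <- "GGGGGAAAACCCCC"
  locus <- make_locus(id = "x", start = 100L, end = 114L, strand = "-",
                      precursor_seq = prec)
  # transcript offset for genomic pos 104 is 114 - 1 - 104 = 9 -> base "C"
  rec <- delta_delta_g(locus, make_snp(pos = 104L, ref = "T", alt = "G"),
                       m, fold_fun = fold_exhaustive)
  expect_identical(rec$ddg, 0)
  expect_identical(rec$effect_class, "unchanged")
})

test_that("a stem-breaking substitution destabilizes a perfect hairpin", {
  m <- default_model()
  prec <- "GGGGGAAAACCCCC" # perfect 5-pair stem, tetraloop
  locus <- make_locus(id = "x", chrom = "chr1", start = 100L, end = 114L,
                      strand = "+", precursor_seq = prec)
  # G -> A at stem position 2 creates an A:C opposition
  rec <- delta_delta_g(locus, make_snp(pos = 102L, ref = "G", alt = "A"),
                       m, fold_fun = fold_exhaustive)
  expect_identical(rec$context, "stem")
  expect_gt(rec$ddg, 0)
  # internal DP agrees with the enumeration route
  rec2 <- delta_delta_g(locus, make_snp(pos = 102L, ref = "G", alt = "A"), m)
  expect_equal(rec$ddg, rec2$ddg)
})

test_that("repairing a stem mismatch stabilizes the hairpin", {
  m <- default_model()
  prec_mm <- "GGAGGAAAACCCCC" # A:C opposition mid-stem
  locus <- make_locus(id = "x", start = 100L, end = 114L, strand = "+",
                      precursor_seq = prec_mm)
  # A -> G creates a G:C pair (the stabilizing stem-SNP archetype)
  rec <- delta_delta_g(locus, make_snp(pos = 102L, ref = "A", alt = "G"),
                       m, fold_fun = fold_exhaustive)
  expect_lt(rec$ddg, 0)
  # monotonicity at the MFE level: the repaired sequence folds at least
  # as low as the mismatched one
  e_mm <- fold_exhaustive(prec_mm, m)$mfe
  e_wc <- fold_exhaustive("GGGGGAAAACCCCC", m)$mfe
  expect_lt(e_wc, e_mm)
})

test_that("a loop substitution creating no pairing leaves ddG ~ 0", {
  m <- default_model()
  prec <- "GGGGGAAAACCCCC"
  locus <- make_locus(id = "x", start = 100L, end = 114L, strand = "+",
                      precursor_seq = prec)
  # loop position (offset 6), A -> C: no new pairing with the G/C stem
  # on the 5' side at hairpin-feasible distance
  rec <- delta_delta_g(locus, make_snp(pos = 106L, ref = "A", alt = "C"),
                       m, fold_fun = fold_exhaustive)
  expect_identical(rec$context, "loop")
  expect_lte(abs(rec$ddg), 0.3)
})

test_that("ddg_table folds each locus once and covers all precursor SNPs", {
  m <- default_model()
  study <- small_study()
  asn <- assign_regions(study)
  dd <- ddg_table(study$loci, study$variants, m)
  n_alts <- sum(lengths(strsplit(
    asn$alt[asn$region_label %in% c("mature", "precursor_nonmature")], ","
  )))
  expect_identical(nrow(dd), n_alts)
  expect_true(all(dd$effect_class %in%
    c("destabilizing", "stabilizing", "slight", "unchanged")))
  expect_true(all(dd$context %in% c("stem", "loop")))
  # SNP outside the precursor violates the contract
  lc <- study$loci[1, ]
  expect_error(
    delta_delta_g(lc, make_snp(chrom = lc$chrom, pos = lc$end + 5L), m),
    "overlap"
  )
})

test_that("energy parameters fail validation when tampered with", {
  bad <- default_model()
  bad$stack["CG", "GC"] <- 1.0
  expect_error(mirvar:::validate_energy_model(bad), "<= 0")
  bad2 <- default_model()
  bad2$hairpin["4"] <- -1
  expect_error(mirvar:::validate_energy_model(bad2), ">= 0")
})
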