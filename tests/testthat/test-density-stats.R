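# Density bookkeeping, ANOVA with letter groups, substitution spectrum.

test_that("per-locus densities are count over region length", {
  matures <- data.frame(
    locus_id = "mir-1", mature_id = "mir-1-5p", offset = 10L, length = 21L,
    seq = paste(rep("A", 21), collapse = ""), stringsAsFactors = FALSE
  )
  locus <- make_locus(id = "mir-1", start = 1000L, end = 1100L)
  variants <- rbind(make_snp(pos = 1040L), make_snp(pos = 1060L))
  asn <- assign_regions(loci = locus, matures = matures, variants = variants)
  tab <- density_by_region(asn, locus, matures)
  d <- tab$per_locus
  expect_equal(d$density[d$group == "precursor"], 0.02)
  expect_equal(d$bases[d$group == "mature"], 21)
  expect_equal(sum(d$snp_count[d$group %in% c("up_flank", "down_flank")]), 0)
})

test_that("zero-SNP loci are part of the averages with density 0", {
  study <- small_study()
  asn <- assign_regions(study)[0, ] # drop all assignments
  tab <- density_by_region(asn, study$loci, study$matures)
  expect_true(all(tab$summary$mean == 0))
  expect_true(all(tab$summary$se == 0))
  expect_identical(
    sum(tab$per_locus$group == "precursor"), nrow(study$loci)
  )
  expect_error(density_by_region(asn, study$loci[0, ], study$matures),
               "empty")
})

test_that("region counts conserve across disjoint labels", {
  study <- small_study()
  asn <- assign_regions(study)
  tab <- density_by_region(asn, study$loci, study$matures)
  d <- tab$per_locus
  # precursor (mature + nonmature) + flanks == all assigned SNPs
  tot <- sum(d$snp_count[d$group %in% c("precursor", "up_flank",
                                        "down_flank")])
  expect_identical(tot, nrow(asn))
  # the mature group is a subset of the precursor group
  expect_identical(sum(d$snp_count[d$group == "mature"]),
                   sum(asn$region_label == "mature"))
  # excluding the densest loci never increases the total SNP count
  prec <- d[d$group == "precursor", ]
  ord <- prec$locus_id[order(-prec$density)]
  totals <- vapply(0:5, function(k) {
    sum(prec$snp_count[!prec$locus_id %in% ord[seq_len(k)]])
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("one-way ANOVA matches the hand-computed F", {
  # between-group MS = 3 * var(c(2, 5, 8)) = 27; within-group MS = 1
  res <- anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(res$F, 27)
  expect_equal(res$F, unname(summary(aov(
    y ~ g, data.frame(y = 1:9, g = rep(c("a", "b", "c"), each = 3))
  ))[[1]][["F value"]][1]))
  expect_lt(res$p, 0.05)
  expect_identical(length(unique(res$letters)), 3L)
})

test_that("degenerate identical groups give F = 0, p = 1, one letter", {
  res <- anova_oneway(list(a = c(0, 0, 0), b = c(0, 0, 0)))
  expect_identical(res$F, 0)
  expect_identical(res$p, 1)
  expect_identical(unname(res$letters), c("a", "a"))
})

test_that("letter groups respect the pairwise Holm-adjusted tests", {
  set.seed(13)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    groups <- lapply(seq_len(k), function(i) {
      rnorm(sample(4:10, 1), mean = sample(0:3, 1))
    })
    names(groups) <- paste0("g", seq_len(k))
    res <- anova_oneway(groups)
    share <- outer(res$letters, res$letters, function(x, y) {
      mapply(function(a, b) {
        any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
      }, x, y)
    })
    sig <- res$pairwise_p < 0.05
    # significant pairs never share; non-significant pairs always share
    expect_false(any(share & sig))
    expect_true(all(share[!sig]))
  }
})

test_that("per-site density divides by matures long enough for the site", {
  matures <- data.frame(
    locus_id = paste0("m", 1:10), mature_id = paste0("m", 1:10, "-5p"),
    offset = 0L, length = 21L,
    seq = paste(rep("A", 21), collapse = ""), stringsAsFactors = FALSE
  )
  asn <- data.frame(
    locus_id = "m1", region_label = "mature", offset = 0L, site = 1L,
    mature_id = "m1-5p", reg_len = 21L, chrom = "chr1", pos = 0L,
    ref = "A", alt = "G", ancestral = "A", pop = "x",
    stringsAsFactors = FALSE
  )
  ps <- per_site_density(asn, matures)
  expect_equal(ps$per_site$density[1], 0.1)
  expect_identical(max(ps$per_site$site), 21L)
  expect_true(all(ps$per_site$n_matures == 10))
})

test_that("sites beyond every mature length are absent", {
  study <- small_study()
  asn <- assign_regions(study)
  ps <- per_site_density(asn, study$matures)
  expect_identical(max(ps$per_site$site), max(study$matures$length))
  expect_true(all(ps$per_site$n_matures[ps$per_site$site >
    min(study$matures$length)] < nrow(study$matures) |
    min(study$matures$length) == max(study$matures$length)))
})

test_that("uniform per-site rates rarely trigger the site ANOVA", {
  # planted rates are uniform across sites, so the per-site ANOVA should
  # accept the null in the large majority of replicates
  set.seed(17)
  rejections <- 0L
  n_rep <- 40L
  matures <- data.frame(
    locus_id = paste0("m", 1:60), mature_id = paste0("m", 1:60),
    offset = 0L, length = 21L,
    seq = paste(rep("A", 21), collapse = ""), stringsAsFactors = FALSE
  )
  for (r in seq_len(n_rep)) {
    hit <- which(runif(60 * 21) < 0.05)
    asn <- data.frame(
      locus_id = matures$locus_id[(hit - 1) %/% 21 + 1],
      region_label = "mature", offset = (hit - 1) %% 21,
      site = as.integer((hit - 1) %% 21 + 1),
      mature_id = matures$mature_id[(hit - 1) %/% 21 + 1],
      reg_len = 21L, chrom = "chr1", pos = hit, ref = "A", alt = "G",
      ancestral = "A", pop = "x", stringsAsFactors = FALSE
    )
    ps <- per_site_density(asn, matures)
    if (ps$anova$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_rep, 0.15)
})

test_that("length-stratified shares partition the mature SNPs", {
  study <- small_study()
  asn <- assign_regions(study)
  ls <- length_stratified_summary(asn, study$matures)
  n_mat <- sum(asn$region_label == "mature")
  expect_equal(sum(ls$snp_count), n_mat)
  if (n_mat > 0) expect_equal(sum(ls$share), 1)
  # single-length degenerate case
  m21 <- study$matures[study$matures$length == 21, , drop = FALSE]
  a21 <- asn[asn$mature_id %in% m21$mature_id &
               asn$region_label == "mature", , drop = FALSE]
  ls21 <- length_stratified_summary(a21, m21)
  if (nrow(a21)) expect_equal(ls21$share[ls21$length == 21], 1)
})

test_that("substitution polarization follows the ancestral allele", {
  # ancestral = ref: direction ref -> alt
  s1 <- substitution_spectrum(make_snp(ref = "C", alt = "T", ancestral = "C"))
  expect_identical(unname(s1$directed["C>T"]), 1L)
  expect_identical(s1$transitions, 1L)
  # ancestral is the alt: direction alt -> ref
  s2 <- substitution_spectrum(make_snp(ref = "C", alt = "T", ancestral = "T"))
  expect_identical(unname(s2$directed["T>C"]), 1L)
  # unknown ancestral: unpolarized, still counted for Ts/Tv
  s3 <- substitution_spectrum(make_snp(ref = "C", alt = "T",
                                       ancestral = NA_character_))
  expect_identical(sum(s3$directed), 0L)
  expect_identical(unname(s3$undirected["C/T"]), 1L)
  expect_identical(s3$transitions, 1L)
  # ancestral matching neither allele: unpolarized fallback
  s4 <- substitution_spectrum(make_snp(ref = "C", alt = "T", ancestral = "G"))
  expect_identical(s4$n_unpolarized, 1L)
})

test_that("equal counts of all 12 directed types give Ts/Tv = 0.5", {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (a in bases) {
    for (b in setdiff(bases, a)) {
      rows[[length(rows) + 1L]] <- make_snp(ref = a, alt = b, ancestral = a)
    }
  }
  sp <- substitution_spectrum(do.call(rbind, rows))
  expect_equal(sp$transition_fraction, 1 / 3)
  expect_equal(sp$tstv_ratio, 0.5)
  expect_identical(sum(sp$directed), sp$n_polarized)
})

test_that("multi-allelic sites expand per derived allele in the spectrum", {
  sp <- substitution_spectrum(make_snp(ref = "A", alt = "G,C",
                                       ancestral = "A"))
  expect_identical(unname(sp$directed["A>G"]), 1L)
  expect_identical(unname(sp$directed["A>C"]), 1L)
  expect_identical(sp$n_polarized, 1L)
})
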