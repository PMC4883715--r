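# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# small all-purpose study: a handful of loci, variants, planted target sites
small_cfg <- function(seed = 11L, ...) {
  sim_config(
    seed = seed, n_chroms = 2L, chrom_len = 60000L, n_loci = 10L,
    n_transcripts = 10L,
    planted_site_spec = data.frame(
      mirna = c(1L, 2L, 3L), mismatches = c(0L, 2L, 0L),
      wobbles = c(0L, 0L, 1L)
    ),
    ...
  )
}

small_study <- function() cached("small_study", simulate_study(small_cfg()))

# larger study used for planted-rate recovery: uniform precursor rate
recovery_cfg <- function(seed = 7L) {
  sim_config(
    seed = seed, n_chroms = 2L, chrom_len = 600000L, n_loci = 500L,
    region_rates = c(
      mature = 0.02, precursor = 0.02, flank = 0.005, background = 0.002
    ),
    tstv_odds = 2.0,
    n_transcripts = 0L
  )
}

recovery_study <- function() {
  cached("recovery_study", simulate_study(recovery_cfg()))
}

default_model <- function() cached("energy_model", energy_model())

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# one-row locus data frame for hand-built cases
make_locus <- function(id = "mir-1", chrom = "chr1", start = 1000L,
                       end = 1100L, strand = "+",
                       precursor_seq = NULL) {
  if (is.null(precursor_seq)) {
    precursor_seq <- paste(rep("A", end - start), collapse = "")
  }
  data.frame(
    id = id, chrom = chrom, start = start, end = end, strand = strand,
    precursor_seq = precursor_seq, conserved = FALSE,
    stringsAsFactors = FALSE
  )
}

make_snp <- function(chrom = "chr1", pos = 1005L, ref = "A", alt = "G",
                     ancestral = ref, pop = "cultivated") {
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, ancestral = ancestral,
    pop = pop, stringsAsFactors = FALSE
  )
}

# brute-force target scan oracle: score every window with score_site()
brute_force_targets <- function(mirnas, transcripts, theta_a = 4,
                                theta_b = 5) {
  out <- list()
  for (mn in names(mirnas)) {
    L <- nchar(mirnas[[mn]])
    for (tn in names(transcripts)) {
      tx <- transcripts[[tn]]
      S <- nchar(tx) - L + 1L
      if (S < 1L) next
      best <- NULL
      for (s0 in 0:(S - 1L)) {
        sc <- score_site(mirnas[[mn]], substr(tx, s0 + 1L, s0 + L),
                         theta_a, theta_b)
        if (sc$consensus &&
            (is.null(best) || sc$score_a < best$score_a)) {
          best <- list(start = s0, score_a = sc$score_a,
                       score_b = sc$score_b)
        }
      }
      if (!is.null(best)) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mn, transcript_id = tn, start = best$start,
          score_a = best$score_a, score_b = best$score_b,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      mirna_id = character(), transcript_id = character(),
      start = integer(), score_a = numeric(), score_b = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}
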