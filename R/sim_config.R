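#' Configuration for a synthetic miRNA-SNP study
#'
#' Bundles every generative parameter of the synthetic study: genome size,
#' hairpin locus geometry, per-region variant rates, the
#' transition:transversion odds, population labels, and the transcriptome
#' with planted target sites. All downstream modules can be exercised on the
#' study this config generates, with the planted truth kept alongside.
#'
#' @param seed integer seed; the whole study is a deterministic function of
#'   the config, including this seed.
#' @param n_chroms number of chromosomes.
#' @param chrom_len length of each chromosome in bases.
#' @param n_loci number of pre-miRNA hairpin loci to embed.
#' @param precursor_len_range integer vector `c(min, max)` of precursor
#'   lengths (nt). Must satisfy `min >= 2 * max mature length + 3` so a
#'   hairpin with a minimal loop can always host a mature arm.
#' @param mature_len_weights named numeric vector of sampling weights over
#'   mature lengths 19..24 nt. Defaults follow the empirical length mix of
#'   rice mature miRNAs (about half 21 nt, then 22 and 24 nt).
#' @param loop_len_range integer `c(min, max)` terminal loop length (>= 3).
#' @param stem_mismatch_rate per-position probability that the 3' arm base
#'   deviates from perfect reverse complementarity with the 5' arm.
#' @param region_rates named numeric vector of per-base variant rates with
#'   entries `mature`, `precursor`, `flank`, `background` (all in \[0,1\]).
#' @param tstv_odds expected transition:transversion count ratio among
#'   simulated variants (> 0). A transition is drawn with probability
#'   `odds/(odds+1)`; the two transversion types split the remainder.
#' @param pop_labels character vector of population tags assigned uniformly
#'   to variants.
#' @param n_transcripts,transcript_len transcriptome size.
#' @param planted_site_spec data frame with integer columns `mirna`
#'   (1-based row index into the study's mature table), `mismatches`,
#'   `wobbles`: one near-complementary target window is embedded per row.
#' @param conserved_fraction fraction of loci whose matures are copied into
#'   the synthetic "other species" reference, making them conserved by
#'   construction.
#' @param min_locus_gap minimum genomic distance between loci (bases);
#'   the default 2 kb keeps matched flanks and 1-kb windows collision-free.
#' @param ancestral_scramble probability that a variant's ancestral allele is
#'   set to the derived allele instead of the reference (0 = perfectly
#'   polarized truth). Use to exercise the unpolarized fallback.
#' @param multiallelic_rate probability that a variant receives a second,
#'   distinct alternate allele.
#' @param gc GC content of background sequence.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_loci = 5, chrom_len = 50000)
#' study <- simulate_study(cfg)
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_len = 100000L,
                       n_loci = 20L,
                       precursor_len_range = c(80L, 160L),
                       mature_len_weights = c(
                         "19" = 0.028, "20" = 0.028, "21" = 0.492,
                         "22" = 0.222, "23" = 0.027, "24" = 0.203
                       ),
                       loop_len_range = c(4L, 8L),
                       stem_mismatch_rate = 0.05,
                       region_rates = c(
                         mature = 0.012, precursor = 0.02,
                         flank = 0.005, background = 0.002
                       ),
                       tstv_odds = 2.46,
                       pop_labels = c("cultivated", "wild"),
                       n_transcripts = 30L,
                       transcript_len = 500L,
                       planted_site_spec = NULL,
                       conserved_fraction = 0.25,
                       min_locus_gap = 2000L,
                       ancestral_scramble = 0,
                       multiallelic_rate = 0,
                       gc = 0.5) {
  if (is.null(planted_site_spec)) {
    planted_site_spec <- data.frame(
      mirna = integer(), mismatches = integer(), wobbles = integer()
    )
  }
  cfg <- structure(
    list(
      seed = as.integer(seed), n_chroms = as.integer(n_chroms),
      chrom_len = as.integer(chrom_len), n_loci = as.integer(n_loci),
      precursor_len_range = as.integer(precursor_len_range),
      mature_len_weights = mature_len_weights,
      loop_len_range = as.integer(loop_len_range),
      stem_mismatch_rate = stem_mismatch_rate,
      region_rates = region_rates,
      tstv_odds = tstv_odds,
      pop_labels = pop_labels,
      n_transcripts = as.integer(n_transcripts),
      transcript_len = as.integer(transcript_len),
      planted_site_spec = planted_site_spec,
      conserved_fraction = conserved_fraction,
      min_locus_gap = as.integer(min_locus_gap),
      ancestral_scramble = ancestral_scramble,
      multiallelic_rate = multiallelic_rate,
      gc = gc
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_chroms >= 1L, cfg$chrom_len >= 1L, cfg$n_loci >= 0L,
    length(cfg$precursor_len_range) == 2L,
    cfg$precursor_len_range[1] <= cfg$precursor_len_range[2],
    length(cfg$loop_len_range) == 2L, cfg$loop_len_range[1] >= 3L,
    cfg$stem_mismatch_rate >= 0, cfg$stem_mismatch_rate <= 1,
    cfg$tstv_odds > 0,
    cfg$conserved_fraction >= 0, cfg$conserved_fraction <= 1,
    cfg$gc > 0, cfg$gc < 1
  )
  need <- c("mature", "precursor", "flank", "background")
  missing <- setdiff(need, names(cfg$region_rates))
  if (length(missing)) {
    stop("region_rates is missing labels: ", paste(missing, collapse = ", "))
  }
  if (any(cfg$region_rates < 0 | cfg$region_rates > 1)) {
    stop("region_rates must all lie in [0, 1]")
  }
  w <- cfg$mature_len_weights
  if (is.null(names(w)) || !all(names(w) %in% as.character(19:24)) ||
      any(w < 0) || sum(w) <= 0) {
    stop("mature_len_weights must be non-negative weights named within 19..24")
  }
  max_mature <- max(as.integer(names(w)[w > 0]))
  if (cfg$precursor_len_range[1] < 2L * max_mature + 3L) {
    stop(
      "precursor_len_range minimum (", cfg$precursor_len_range[1],
      ") must be >= 2 * max mature length + 3 = ", 2L * max_mature + 3L
    )
  }
  sp <- cfg$planted_site_spec
  if (!is.data.frame(sp) ||
      !all(c("mirna", "mismatches", "wobbles") %in% names(sp))) {
    stop("planted_site_spec must be a data frame with columns mirna, mismatches, wobbles")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(
    "<sim_config> seed", x$seed, "|", x$n_chroms, "chrom x", x$chrom_len,
    "bp |", x$n_loci, "loci |", x$n_transcripts, "transcripts\n"
  )
  cat(
    "  region rates:",
    paste(names(x$region_rates), signif(x$region_rates, 3),
      sep = "=", collapse = " "
    ),
    "| Ts:Tv odds", x$tstv_odds, "\n"
  )
  invisible(x)
}
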