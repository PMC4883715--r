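# Synthetic study generation: toy genome with embedded hairpin loci,
# variants at controlled per-region rates, and a transcriptome with
# planted near-complementary target sites. The planted truth travels with
# the study so downstream estimates can be checked against it.

#' Generate a toy genome with embedded pre-miRNA hairpin loci
#'
#' Each locus is built as 5' arm + terminal loop + reverse complement of the
#' arm (with per-position mismatches at `stem_mismatch_rate`), annotated with
#' one mature miRNA inside one stem arm, and embedded at a jittered,
#' non-overlapping genomic position; about half the loci go on the minus
#' strand. Loci are kept at least `min_locus_gap` apart so matched flanks
#' and 1-kb windows never collide.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `mirna_study` with `genome`, `loci`, `matures`
#'   and `truth` populated (`variants` and `transcripts` still `NULL`).
#' @export
generate_genome_with_loci <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- vapply(
    chrom_names, function(ch) random_dna(cfg$chrom_len, cfg$gc), character(1)
  )

  max_len <- cfg$precursor_len_range[2]
  margin <- cfg$min_locus_gap + max_len
  slot_len <- max_len + cfg$min_locus_gap
  usable <- cfg$chrom_len - 2L * margin
  slots_per_chrom <- max(0L, usable %/% slot_len)
  if (slots_per_chrom * cfg$n_chroms < cfg$n_loci) {
    stop(
      "cannot place ", cfg$n_loci, " non-overlapping loci: capacity is ",
      slots_per_chrom * cfg$n_chroms,
      " (increase chrom_len/n_chroms or reduce min_locus_gap)"
    )
  }

  lens <- as.integer(names(cfg$mature_len_weights))
  wts <- cfg$mature_len_weights

  loci <- vector("list", cfg$n_loci)
  matures <- vector("list", cfg$n_loci)
  for (i in seq_len(cfg$n_loci)) {
    L <- sample(cfg$precursor_len_range[1]:cfg$precursor_len_range[2], 1L)
    loop <- sample(cfg$loop_len_range[1]:cfg$loop_len_range[2], 1L)
    arm <- (L - loop) %/% 2L
    loop <- L - 2L * arm # absorb parity into the loop

    arm5 <- random_dna(arm)
    loop_seq <- random_dna(loop)
    arm3 <- revcomp_dna(arm5)
    if (cfg$stem_mismatch_rate > 0) {
      hit <- which(runif(arm) < cfg$stem_mismatch_rate)
      if (length(hit)) {
        a3 <- seq_chars(arm3)
        for (p in hit) {
          a3[p] <- sample(setdiff(c("A", "C", "G", "T"), a3[p]), 1L)
        }
        arm3 <- paste(a3, collapse = "")
      }
    }
    prec_dna <- paste0(arm5, loop_seq, arm3)

    m_len <- if (length(lens) == 1L) lens else sample(lens, 1L, prob = wts)
    arm_choice <- sample(c("5p", "3p"), 1L)
    off_in_arm <- sample.int(arm - m_len + 1L, 1L) - 1L
    m_off <- if (arm_choice == "5p") off_in_arm else arm + loop + off_in_arm

    chrom_i <- ((i - 1L) %% cfg$n_chroms) + 1L
    slot_i <- ((i - 1L) %/% cfg$n_chroms)
    jitter <- sample.int(max_len - L + 1L, 1L) - 1L
    start <- margin + slot_i * slot_len + jitter
    end <- start + L
    strand <- sample(c("+", "-"), 1L)

    placed <- if (strand == "+") prec_dna else revcomp_dna(prec_dna)
    substr(genome[chrom_i], start + 1L, end) <- placed

    id <- sprintf("syn-mir-%03d", i)
    loci[[i]] <- data.frame(
      id = id, chrom = chrom_names[chrom_i], start = start, end = end,
      strand = strand, precursor_seq = dna2rna(prec_dna),
      conserved = FALSE, stringsAsFactors = FALSE
    )
    matures[[i]] <- data.frame(
      locus_id = id, mature_id = paste0(id, "-", arm_choice),
      offset = m_off, length = m_len,
      seq = dna2rna(substr(prec_dna, m_off + 1L, m_off + m_len)),
      stringsAsFactors = FALSE
    )
  }
  loci <- if (cfg$n_loci) do.call(rbind, loci) else empty_loci_df()
  matures <- if (cfg$n_loci) do.call(rbind, matures) else empty_matures_df()

  n_cons <- floor(cfg$conserved_fraction * cfg$n_loci)
  cons_ids <- character(0)
  cons_ref <- character(0)
  if (n_cons > 0) {
    cons_ids <- sort(sample(loci$id, n_cons))
    loci$conserved <- loci$id %in% cons_ids
    keep <- matures$locus_id %in% cons_ids
    cons_ref <- setNames(
      matures$seq[keep], paste0("othersp-", matures$mature_id[keep])
    )
  }

  structure(
    list(
      cfg = cfg, genome = genome, loci = loci, matures = matures,
      variants = NULL, transcripts = NULL,
      truth = list(
        region_rates = cfg$region_rates, tstv_odds = cfg$tstv_odds,
        conserved_ids = cons_ids, conserved_reference = cons_ref,
        planted_sites = NULL
      )
    ),
    class = "mirna_study"
  )
}

empty_loci_df <- function() {
  data.frame(
    id = character(), chrom = character(), start = integer(), end = integer(),
    strand = character(), precursor_seq = character(), conserved = logical(),
    stringsAsFactors = FALSE
  )
}

empty_matures_df <- function() {
  data.frame(
    locus_id = character(), mature_id = character(), offset = integer(),
    length = integer(), seq = character(), stringsAsFactors = FALSE
  )
}

empty_variants_df <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), ancestral = character(), pop = character(),
    stringsAsFactors = FALSE
  )
}

# Genomic intervals (0-based half-open) of the simulation region classes:
# mature, precursor (non-mature part), matched flank. Used only by the
# generator; analysis-side region assignment lives in locus_mapping.
sim_region_intervals <- function(study) {
  loci <- study$loci
  mt <- study$matures
  out <- list()
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    L <- lc$end - lc$start
    m <- mt[mt$locus_id == lc$id, ]
    # mature genomic interval from precursor offset, strand-aware
    if (lc$strand == "+") {
      ms <- lc$start + m$offset
    } else {
      ms <- lc$end - m$offset - m$length
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = lc$chrom, start = ms, end = ms + m$length, label = "mature",
      stringsAsFactors = FALSE
    )
    out[[length(out) + 1L]] <- data.frame(
      chrom = lc$chrom,
      start = c(lc$start - L, lc$end), end = c(lc$start, lc$end + L),
      label = "flank", stringsAsFactors = FALSE
    )
    out[[length(out) + 1L]] <- data.frame(
      chrom = lc$chrom, start = lc$start, end = lc$end, label = "precursor",
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(),
      label = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

# sample n distinct 0-based positions uniformly from a set of intervals
sample_interval_positions <- function(iv, n) {
  if (n == 0L || !nrow(iv)) {
    return(iv[0, c("chrom", "start")])
  }
  widths <- iv$end - iv$start
  total <- sum(widths)
  stopifnot(n <= total)
  flat <- sort(sample.int(total, n)) # 1-based offsets into concatenation
  cum <- cumsum(widths)
  idx <- findInterval(flat - 1L, c(0L, cum), rightmost.closed = FALSE)
  pos <- iv$start[idx] + (flat - 1L) - c(0L, cum)[idx]
  data.frame(chrom = iv$chrom[idx], start = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Simulate variants over a synthetic study at per-region rates
#'
#' Every base carries an independent per-base variant probability given by
#' its region class (`mature`, non-mature `precursor`, matched `flank`, or
#' `background`); mature takes precedence over precursor, precursor over
#' flank. The alternate allele is a transition with probability
#' `tstv_odds / (tstv_odds + 1)`, otherwise one of the two transversions
#' with equal probability. Ancestral alleles equal the reference unless
#' `ancestral_scramble > 0`; each variant gets a population tag drawn
#' uniformly from `pop_labels`.
#'
#' @param study a `mirna_study` with genome and loci populated.
#' @param cfg a [sim_config()]; defaults to the one stored in the study.
#' @return the study with `variants` populated (one row per site; the `alt`
#'   column is comma-separated when `multiallelic_rate > 0` fires).
#' @export
simulate_snps <- function(study, cfg = study$cfg) {
  validate_sim_config(cfg)
  stopifnot(inherits(study, "mirna_study"), !is.null(study$genome))
  set.seed(cfg$seed + 104729L)

  iv <- sim_region_intervals(study)
  gr_all <- GenomicRanges::GRanges(
    seqnames = names(study$genome),
    ranges = IRanges::IRanges(start = 1L, width = nchar(study$genome))
  )
  # precedence: mature > precursor > flank; carve overlaps out
  take <- function(lbl) {
    sub <- iv[iv$label == lbl, , drop = FALSE]
    if (!nrow(sub)) {
      return(GenomicRanges::GRanges())
    }
    GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    ))
  }
  gr_mat <- take("mature")
  gr_pre <- GenomicRanges::setdiff(take("precursor"), gr_mat)
  gr_fla <- GenomicRanges::setdiff(
    take("flank"), GenomicRanges::union(gr_mat, gr_pre)
  )
  covered <- GenomicRanges::reduce(c(gr_mat, gr_pre, gr_fla))
  gr_bg <- GenomicRanges::setdiff(gr_all, covered)

  gr2iv <- function(gr) {
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr), stringsAsFactors = FALSE
    )
  }
  classes <- list(
    mature = gr2iv(gr_mat), precursor = gr2iv(gr_pre),
    flank = gr2iv(gr_fla), background = gr2iv(gr_bg)
  )

  picked <- list()
  for (lbl in names(classes)) {
    civ <- classes[[lbl]]
    B <- sum(civ$end - civ$start)
    r <- unname(cfg$region_rates[[lbl]])
    n <- if (B > 0L && r > 0) rbinom(1L, B, r) else 0L
    picked[[lbl]] <- sample_interval_positions(civ, n)
  }
  sites <- do.call(rbind, picked)
  if (!nrow(sites)) {
    study$variants <- empty_variants_df()
    return(study)
  }
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]

  ref <- vapply(
    seq_len(nrow(sites)),
    function(k) substr(study$genome[[sites$chrom[k]]],
                       sites$start[k] + 1L, sites$start[k] + 1L),
    character(1)
  )
  p_ts <- cfg$tstv_odds / (cfg$tstv_odds + 1)
  draw_alt <- function(b, avoid = character(0)) {
    cands_ts <- setdiff(transition_of(b), avoid)
    cands_tv <- setdiff(transversions_of(b), avoid)
    if (length(cands_ts) && runif(1) < p_ts) {
      cands_ts
    } else if (length(cands_tv)) {
      cands_tv[sample.int(length(cands_tv), 1L)]
    } else {
      cands_ts
    }
  }
  alt <- character(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    a1 <- draw_alt(ref[k])
    if (cfg$multiallelic_rate > 0 && runif(1) < cfg$multiallelic_rate) {
      a2 <- draw_alt(ref[k], avoid = a1)
      alt[k] <- paste(sort(c(a1, a2)), collapse = ",")
    } else {
      alt[k] <- a1
    }
  }
  ancestral <- ref
  if (cfg$ancestral_scramble > 0) {
    flip <- runif(nrow(sites)) < cfg$ancestral_scramble
    first_alt <- sub(",.*$", "", alt)
    ancestral[flip] <- first_alt[flip]
  }
  pop <- sample(cfg$pop_labels, nrow(sites), replace = TRUE)

  study$variants <- data.frame(
    chrom = sites$chrom, pos = sites$start, ref = ref, alt = alt,
    ancestral = ancestral, pop = pop, stringsAsFactors = FALSE
  )
  rownames(study$variants) <- NULL
  study
}

# Build a target window: reverse complement of the mature (DNA), with
# exactly `wobbles` G:U-creating changes and `mismatches` true mismatches.
make_target_window <- function(mature_rna, mismatches = 0L, wobbles = 0L) {
  L <- nchar(mature_rna)
  if (mismatches + wobbles >= L) {
    stop("requested mismatches + wobbles (", mismatches + wobbles,
         ") must be < mature length (", L, ")")
  }
  mir <- seq_chars(mature_rna)
  win <- seq_chars(revcomp_dna(rna2dna(mature_rna)))
  # window position w faces miRNA position L - w + 1
  mir_at <- function(w) mir[L - w + 1L]
  # wobble-eligible: miRNA base G (target C -> T) or U (target A -> G)
  elig_w <- which(vapply(seq_len(L), function(w) mir_at(w) %in% c("G", "U"),
                         logical(1)))
  if (wobbles > length(elig_w)) {
    stop("cannot place ", wobbles, " wobbles: only ", length(elig_w),
         " wobble-eligible positions")
  }
  wpos <- if (wobbles) sort(sample(elig_w, wobbles)) else integer(0)
  for (w in wpos) win[w] <- if (mir_at(w) == "G") "T" else "G"
  mpos_cand <- setdiff(seq_len(L), wpos)
  mpos <- if (mismatches) sort(sample(mpos_cand, mismatches)) else integer(0)
  for (w in mpos) {
    comp <- comp_base(rna2dna(mir_at(w)))
    wob <- if (mir_at(w) == "G") "T" else if (mir_at(w) == "U") "G" else NA
    bad <- c(comp, wob)
    win[w] <- sample(setdiff(c("A", "C", "G", "T"), bad[!is.na(bad)]), 1L)
  }
  list(window = paste(win, collapse = ""),
       mismatch_pos = mpos, wobble_pos = wpos)
}

#' Synthesize a transcriptome with planted miRNA target sites
#'
#' Generates random transcripts and, for each row of
#' `cfg$planted_site_spec`, embeds a window equal to the reverse complement
#' of the chosen mature miRNA carrying exactly the requested number of
#' mismatches and G:U wobbles, at a recorded position.
#'
#' @inheritParams simulate_snps
#' @return the study with `transcripts` (named DNA strings) populated and
#'   `truth$planted_sites` recording each embedded window.
#' @export
synthesize_transcriptome <- function(study, cfg = study$cfg) {
  validate_sim_config(cfg)
  stopifnot(inherits(study, "mirna_study"))
  set.seed(cfg$seed + 224737L)

  tx <- vapply(
    seq_len(cfg$n_transcripts),
    function(i) random_dna(cfg$transcript_len, cfg$gc), character(1)
  )
  names(tx) <- sprintf("tx-%03d", seq_len(cfg$n_transcripts))

  spec <- cfg$planted_site_spec
  planted <- NULL
  if (nrow(spec)) {
    if (!nrow(study$matures)) stop("no mature miRNAs to plant sites for")
    if (any(spec$mirna < 1L | spec$mirna > nrow(study$matures))) {
      stop("planted_site_spec$mirna out of range 1..", nrow(study$matures))
    }
    rows <- vector("list", nrow(spec))
    used <- lapply(tx, function(x) integer(0)) # occupied starts per transcript
    for (k in seq_len(nrow(spec))) {
      m <- study$matures[spec$mirna[k], ]
      w <- make_target_window(m$seq, spec$mismatches[k], spec$wobbles[k])
      L <- nchar(w$window)
      ti <- ((k - 1L) %% cfg$n_transcripts) + 1L
      # avoid overlapping a previously planted window on this transcript
      repeat {
        s0 <- sample.int(cfg$transcript_len - L + 1L, 1L) - 1L
        clash <- any(abs(used[[ti]] - s0) < L + 1L)
        if (!clash) break
      }
      used[[ti]] <- c(used[[ti]], s0)
      substr(tx[ti], s0 + 1L, s0 + L) <- w$window
      rows[[k]] <- data.frame(
        transcript = names(tx)[ti], start = s0, mirna = spec$mirna[k],
        mature_id = m$mature_id, mismatches = spec$mismatches[k],
        wobbles = spec$wobbles[k], stringsAsFactors = FALSE
      )
    }
    planted <- do.call(rbind, rows)
  }
  study$transcripts <- tx
  study$truth$planted_sites <- planted
  study
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_genome_with_loci()],
#' [simulate_snps()] and [synthesize_transcriptome()].
#'
#' @param cfg a [sim_config()].
#' @return a fully populated `mirna_study`.
#' @export
simulate_study <- function(cfg) {
  study <- generate_genome_with_loci(cfg)
  study <- simulate_snps(study, cfg)
  synthesize_transcriptome(study, cfg)
}

#' @export
print.mirna_study <- function(x, ...) {
  cat(
    "<mirna_study>", length(x$genome), "chromosome(s),",
    nrow(x$loci), "loci,",
    if (is.null(x$variants)) "variants: <not simulated>," else
      paste(nrow(x$variants), "variants,"),
    if (is.null(x$transcripts)) "transcripts: <none>" else
      paste(length(x$transcripts), "transcripts"), "\n"
  )
  invisible(x)
}

#' Reverse-complement an entire study (strand-flip transform)
#'
#' Reverse-complements every chromosome, mirrors all genomic coordinates,
#' flips locus strands and complements variant alleles. Locus-relative
#' annotation (precursor sequence, mature offsets) is unchanged, so every
#' region assignment (label, offset) must be invariant under this transform;
#' this is the strand-symmetry property used in the test suite.
#'
#' @param study a `mirna_study`.
#' @return the flipped study.
#' @export
flip_study <- function(study) {
  clen <- nchar(study$genome)
  study$genome <- vapply(study$genome, revcomp_dna, character(1))
  lc <- study$loci
  n <- clen[lc$chrom]
  new_start <- n - lc$end
  lc$end <- n - lc$start
  lc$start <- new_start
  lc$strand <- ifelse(lc$strand == "+", "-", "+")
  study$loci <- lc
  if (!is.null(study$variants) && nrow(study$variants)) {
    v <- study$variants
    v$pos <- clen[v$chrom] - 1L - v$pos
    v$ref <- comp_base(v$ref)
    v$alt <- vapply(
      strsplit(v$alt, ",", fixed = TRUE),
      function(a) paste(comp_base(a), collapse = ","), character(1)
    )
    v$ancestral <- comp_base(v$ancestral)
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    rownames(v) <- NULL
    study$variants <- v
  }
  study
}
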