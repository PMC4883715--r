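# SNP-type mature miRNAs and target-spectrum alteration. Targets are
# scored by two independent rule sets and only sites accepted by both
# ("consensus") count; gain/loss is at transcript-id granularity.

#' Enumerate SNP-type mature miRNAs (SmiRNAs)
#'
#' Projects each mature-overlapping SNP onto its mature miRNA, one SmiRNA
#' per (mature, SNP, alternate allele). The allele is substituted
#' strand-aware (complemented for minus-strand loci); an alternate equal
#' to the existing transcript base is skipped.
#'
#' @param assignments assignment data frame (mature rows are used).
#' @param loci loci data frame.
#' @param matures mature table.
#' @return data frame: `smirna_id`, `mature_id`, `locus_id`, `seq`, `site`,
#'   `wild_base`, `derived_base`, `chrom`, `pos`, `ref`, `alt`.
#' @export
enumerate_smirnas <- function(assignments, loci, matures) {
  a <- assignments[assignments$region_label == "mature", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(a))) {
    row <- a[i, ]
    m <- matures[matures$mature_id == row$mature_id, ]
    lc <- loci[loci$id == row$locus_id, ]
    site <- row$site
    wild_base <- substr(m$seq, site, site)
    for (alt in strsplit(row$alt, ",", fixed = TRUE)[[1]]) {
      derived <- dna2rna(if (lc$strand == "+") alt else comp_base(alt))
      if (derived == wild_base) next
      s <- m$seq
      substr(s, site, site) <- derived
      out[[length(out) + 1L]] <- data.frame(
        smirna_id = paste0(m$mature_id, ":", site, wild_base, ">", derived),
        mature_id = m$mature_id, locus_id = row$locus_id, seq = s,
        site = site, wild_base = wild_base, derived_base = derived,
        chrom = row$chrom, pos = row$pos, ref = row$ref, alt = alt,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      smirna_id = character(), mature_id = character(),
      locus_id = character(), seq = character(), site = integer(),
      wild_base = character(), derived_base = character(),
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Per-position complementarity between a miRNA and a same-length target
# window, both 5'->3'. Window position w faces miRNA position
# p = L - w + 1. Returns, indexed by miRNA position p: "match",
# "wobble" (G:U), or "mismatch".
pairing_classes <- function(mirna, window) {
  mir <- seq_chars(normalize_rna(mirna))
  win <- seq_chars(normalize_rna(window))
  L <- length(mir)
  stopifnot(length(win) == L)
  tgt <- rev(win) # tgt[p] faces mir[p]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  cls <- ifelse(tgt == comp[mir], "match",
    ifelse((mir == "G" & tgt == "U") | (mir == "U" & tgt == "G"),
      "wobble", "mismatch"
    )
  )
  unname(cls)
}

#' Score a miRNA against a candidate target window
#'
#' Two rule sets over the per-position complementarity (positions are
#' 1-based from the miRNA 5' end):
#' * Scheme A (weighted penalty): mismatch 1.0, G:U wobble 0.5, both
#'   doubled at positions 2-13; hit iff penalty <= `theta_a` (default 4.0).
#' * Scheme B (seed + cleavage site): hit iff mismatches + wobbles at
#'   positions 2-8 total <= 1, no mismatch at positions 10-11, and the
#'   unweighted penalty (mismatch 1.0, wobble 0.5) <= `theta_b`
#'   (default 5.0).
#'
#' @param mirna miRNA sequence, 5'->3' (RNA).
#' @param window same-length candidate site on the transcript, 5'->3'.
#' @param theta_a,theta_b acceptance thresholds.
#' @return list: `score_a`, `hit_a`, `score_b`, `hit_b`, `consensus`,
#'   and `positions` (per-miRNA-position class).
#' @export
score_site <- function(mirna, window, theta_a = 4.0, theta_b = 5.0) {
  cls <- pairing_classes(mirna, window)
  L <- length(cls)
  p <- seq_len(L)
  base_pen <- ifelse(cls == "mismatch", 1, ifelse(cls == "wobble", 0.5, 0))
  wt <- ifelse(p >= 2 & p <= 13, 2, 1)
  score_a <- sum(base_pen * wt)
  score_b <- sum(base_pen)
  seed_defects <- sum(cls[p >= 2 & p <= 8] != "match")
  cleavage_ok <- !any(cls[p %in% c(10, 11)] == "mismatch")
  hit_a <- score_a <= theta_a
  hit_b <- seed_defects <= 1 && cleavage_ok && score_b <= theta_b
  list(
    score_a = score_a, hit_a = hit_a, score_b = score_b, hit_b = hit_b,
    consensus = hit_a && hit_b, positions = cls
  )
}

# Vectorized consensus scan of one miRNA over one transcript; returns a
# data frame of all consensus windows (0-based starts).
scan_transcript <- function(mirna, tx_chars, theta_a, theta_b) {
  mir <- seq_chars(normalize_rna(mirna))
  L <- length(mir)
  S <- length(tx_chars) - L + 1L
  if (S < 1L) {
    return(NULL)
  }
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  # matrix [position p, window s]: target char facing miRNA position p
  idx <- outer(L - seq_len(L) + 1L, seq_len(S) - 1L, "+")
  tgt <- matrix(tx_chars[idx], nrow = L)
  mism <- tgt != comp[mir] &
    !((mir == "G") & (tgt == "U")) & !((mir == "U") & (tgt == "G"))
  wob <- ((mir == "G") & (tgt == "U")) | ((mir == "U") & (tgt == "G"))
  base_pen <- mism * 1 + wob * 0.5
  wt <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  score_a <- colSums(base_pen * wt)
  score_b <- colSums(base_pen)
  seed <- seq_len(L) >= 2 & seq_len(L) <= 8
  seed_defects <- colSums(mism[seed, , drop = FALSE]) +
    colSums(wob[seed, , drop = FALSE])
  cleave <- seq_len(L) %in% c(10L, 11L)
  cleavage_bad <- colSums(mism[cleave, , drop = FALSE]) > 0
  hit <- (score_a <= theta_a) &
    (seed_defects <= 1) & !cleavage_bad & (score_b <= theta_b)
  if (!any(hit)) {
    return(NULL)
  }
  data.frame(
    start = which(hit) - 1L, score_a = score_a[hit], score_b = score_b[hit],
    stringsAsFactors = FALSE
  )
}

#' Predict consensus targets of miRNAs over a transcriptome
#'
#' Scores every window of every transcript under both schemes and keeps
#' windows accepted by both ("consensus"). For set-level comparisons,
#' overlapping candidate windows on one transcript are collapsed to the
#' best-scoring one per (miRNA, transcript) — lowest scheme-A penalty,
#' ties to the smallest start.
#'
#' @param mirnas named character vector of miRNA sequences (RNA, 5'->3').
#' @param transcripts named character vector of transcript sequences
#'   (DNA or RNA, 5'->3'); transcripts shorter than the miRNA are skipped.
#' @param theta_a,theta_b scheme thresholds (see [score_site()]).
#' @param collapse collapse to one best site per (miRNA, transcript)?
#' @return data frame of hits: `mirna_id`, `transcript_id`, `start`
#'   (0-based), `score_a`, `score_b`, `consensus`.
#' @export
predict_targets <- function(mirnas, transcripts, theta_a = 4.0,
                            theta_b = 5.0, collapse = TRUE) {
  if (!length(transcripts)) stop("empty transcriptome")
  if (is.null(names(mirnas))) names(mirnas) <- paste0("mir", seq_along(mirnas))
  tx_chars <- lapply(transcripts, function(x) {
    seq_chars(normalize_rna(x))
  })
  out <- list()
  for (mn in names(mirnas)) {
    for (tn in names(transcripts)) {
      hits <- scan_transcript(mirnas[[mn]], tx_chars[[tn]], theta_a, theta_b)
      if (is.null(hits)) next
      if (collapse) {
        hits <- hits[order(hits$score_a, hits$start), , drop = FALSE][1, ,
          drop = FALSE
        ]
      }
      hits$mirna_id <- mn
      hits$transcript_id <- tn
      out[[length(out) + 1L]] <- hits
    }
  }
  if (!length(out)) {
    return(data.frame(
      mirna_id = character(), transcript_id = character(), start = integer(),
      score_a = numeric(), score_b = numeric(), consensus = logical(),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res$consensus <- TRUE
  res <- res[, c("mirna_id", "transcript_id", "start", "score_a", "score_b",
                 "consensus")]
  rownames(res) <- NULL
  res
}

#' Gained and lost targets between a wild-type miRNA and its SmiRNA
#'
#' At transcript-id granularity: gained = targets of the SNP-type not
#' targeted by the wild type; lost = targets of the wild type not targeted
#' by the SNP-type. Both hit sets must come from the same transcriptome
#' and thresholds.
#'
#' @param wild_hits,smirna_hits hit data frames from [predict_targets()]
#'   (each for one miRNA).
#' @return object of class `target_delta`: list(`gained`, `lost`)
#'   character vectors of transcript ids.
#' @export
target_delta <- function(wild_hits, smirna_hits) {
  w <- unique(wild_hits$transcript_id)
  s <- unique(smirna_hits$transcript_id)
  structure(
    list(gained = sort(setdiff(s, w)), lost = sort(setdiff(w, s))),
    class = "target_delta"
  )
}

#' @export
print.target_delta <- function(x, ...) {
  cat("<target_delta>", length(x$gained), "gained /", length(x$lost),
      "lost\n")
  invisible(x)
}

#' Target deltas for every SmiRNA in a study
#'
#' Predicts consensus targets for all wild-type matures and all SmiRNAs,
#' then computes per-pair gain/loss sets.
#'
#' @param smirnas output of [enumerate_smirnas()].
#' @param matures mature table.
#' @param transcripts named transcript sequences.
#' @param theta_a,theta_b scheme thresholds.
#' @return list with `wild_hits`, `smirna_hits` (hit tables) and `deltas`
#'   (data frame: `mature_id`, `smirna_id`, `n_gained`, `n_lost`, plus
#'   comma-separated id lists).
#' @export
target_deltas_all <- function(smirnas, matures, transcripts,
                              theta_a = 4.0, theta_b = 5.0) {
  empty_hits <- data.frame(
    mirna_id = character(), transcript_id = character(), start = integer(),
    score_a = numeric(), score_b = numeric(), consensus = logical(),
    stringsAsFactors = FALSE
  )
  wild_ids <- unique(smirnas$mature_id)
  wild_seqs <- setNames(
    matures$seq[match(wild_ids, matures$mature_id)], wild_ids
  )
  wh <- if (length(wild_seqs)) {
    predict_targets(wild_seqs, transcripts, theta_a, theta_b)
  } else {
    empty_hits
  }
  sh <- if (nrow(smirnas)) {
    predict_targets(setNames(smirnas$seq, smirnas$smirna_id), transcripts,
                    theta_a, theta_b)
  } else {
    empty_hits
  }
  deltas <- do.call(rbind, lapply(seq_len(nrow(smirnas)), function(i) {
    mid <- smirnas$mature_id[i]
    sid <- smirnas$smirna_id[i]
    d <- target_delta(
      wh[wh$mirna_id == mid, , drop = FALSE],
      sh[sh$mirna_id == sid, , drop = FALSE]
    )
    data.frame(
      mature_id = mid, smirna_id = sid,
      n_gained = length(d$gained), n_lost = length(d$lost),
      gained = paste(d$gained, collapse = ","),
      lost = paste(d$lost, collapse = ","), stringsAsFactors = FALSE
    )
  }))
  if (is.null(deltas)) {
    deltas <- data.frame(
      mature_id = character(), smirna_id = character(),
      n_gained = integer(), n_lost = integer(), gained = character(),
      lost = character(), stringsAsFactors = FALSE
    )
  }
  list(wild_hits = wh, smirna_hits = sh, deltas = deltas)
}
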