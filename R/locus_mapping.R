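# Locus placement and region assignment. All genomic coordinates are
# 0-based half-open; offsets are reported 5'->3' in the orientation of the
# transcribed precursor ("up" = the 5' side of the hairpin, which is the
# genomic right side for minus-strand loci).

#' Place a precursor sequence on a genome by exact match
#'
#' Finds every position where the DNA transcription of the precursor occurs
#' exactly on the plus strand, or its reverse complement on the minus
#' strand. Heuristic alignment is deliberately not used: only perfect
#' placements are retained downstream, so exact search is sufficient and
#' fully reproducible.
#'
#' @param precursor_seq RNA string (ACGU), length >= 40.
#' @param genome named character vector of chromosome DNA strings.
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`; zero rows means the precursor is unmapped and is
#'   excluded from downstream analysis.
#' @export
map_precursor_exact <- function(precursor_seq, genome) {
  stopifnot(nchar(precursor_seq) >= 40L, length(genome) >= 1L)
  pat_fwd <- Biostrings::DNAString(rna2dna(precursor_seq))
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  out <- list()
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPattern(
        if (strand == "+") pat_fwd else pat_rev, subj
      )
      if (length(m)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

#' Map a set of precursors, keeping every exact placement
#'
#' Multi-mapping precursors contribute one locus copy per placement (ids are
#' suffixed `.1`, `.2`, ...); unmapped precursors are dropped and reported
#' in the `unmapped` attribute.
#'
#' @param precursors named character vector of RNA precursor sequences.
#' @param genome named character vector of chromosome DNA strings.
#' @return a loci data frame (`id`, `chrom`, `start`, `end`, `strand`,
#'   `precursor_seq`, `conserved`) with attribute `unmapped` (character
#'   vector of precursor names with zero placements).
#' @export
map_all_precursors <- function(precursors, genome) {
  rows <- list()
  unmapped <- character(0)
  for (nm in names(precursors)) {
    hits <- map_precursor_exact(precursors[[nm]], genome)
    if (!nrow(hits)) {
      unmapped <- c(unmapped, nm)
      next
    }
    hits$id <- if (nrow(hits) == 1L) nm else paste0(nm, ".", seq_len(nrow(hits)))
    hits$precursor_seq <- precursors[[nm]]
    hits$conserved <- FALSE
    rows[[length(rows) + 1L]] <- hits[, c(
      "id", "chrom", "start", "end", "strand", "precursor_seq", "conserved"
    )]
  }
  loci <- if (length(rows)) do.call(rbind, rows) else empty_loci_df()
  rownames(loci) <- NULL
  attr(loci, "unmapped") <- unmapped
  loci
}

#' Define a region scheme
#'
#' Three ways to carve the neighbourhood of a precursor into labelled
#' regions: `matched_flank` uses flanks whose length equals the precursor's
#' own length; `kb_window` uses fixed windows (default 1 kb) outward from
#' the precursor boundaries; `distance_bins` uses consecutive bins of width
#' `L` (default 150 nt) outward from the mature miRNA boundaries.
#'
#' @param kind one of `"matched_flank"`, `"kb_window"`, `"distance_bins"`.
#' @param L window/bin width in bases (ignored for `matched_flank`, where
#'   the flank length is per-locus).
#' @param n_bins number of distance bins on each side (`distance_bins` only).
#' @return an object of class `region_scheme`.
#' @export
region_scheme <- function(kind = c("matched_flank", "kb_window", "distance_bins"),
                          L = NULL, n_bins = 5L) {
  kind <- match.arg(kind)
  if (is.null(L)) L <- switch(kind, kb_window = 1000L, distance_bins = 150L, NA_integer_)
  if (kind != "matched_flank" && (is.na(L) || L <= 0L)) {
    stop("L must be a positive window/bin width for scheme '", kind, "'")
  }
  structure(list(kind = kind, L = as.integer(L), n_bins = as.integer(n_bins)),
            class = "region_scheme")
}

# Genomic interval of a mature inside its locus, strand-aware.
mature_genomic <- function(locus, offset, length) {
  if (locus$strand == "+") {
    s <- locus$start + offset
  } else {
    s <- locus$end - offset - length
  }
  c(start = s, end = s + length)
}

# One data frame of labelled, disjoint-per-locus regions under a scheme.
# Columns: locus_id, label, chrom, start, end, strand, anchor5 (genomic
# coordinate of the region's 5' end in transcript orientation), reg_len
# (the length offsets are measured against: the full precursor for
# precursor_nonmature, the region width otherwise).
build_regions <- function(loci, matures, scheme) {
  stopifnot(inherits(scheme, "region_scheme"))
  out <- list()
  add <- function(locus, label, s, e, reg_len = e - s, anchor = NULL,
                  mature_id = NA_character_) {
    if (e <= s) return()
    if (is.null(anchor)) anchor <- if (locus$strand == "+") s else e - 1L
    out[[length(out) + 1L]] <<- data.frame(
      locus_id = locus$id, label = label, chrom = locus$chrom,
      start = s, end = e, strand = locus$strand,
      anchor5 = anchor, reg_len = reg_len, mature_id = mature_id,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    L <- lc$end - lc$start
    mt <- matures[matures$locus_id == lc$id, , drop = FALSE]
    mg <- lapply(seq_len(nrow(mt)), function(k) {
      mature_genomic(lc, mt$offset[k], mt$length[k])
    })
    prec_anchor <- if (lc$strand == "+") lc$start else lc$end - 1L

    if (scheme$kind %in% c("matched_flank", "kb_window")) {
      # mature intervals, then the precursor remainder (offsets measured
      # against the full precursor so they are direct precursor offsets)
      for (k in seq_along(mg)) {
        add(lc, "mature", mg[[k]]["start"], mg[[k]]["end"],
            mature_id = mt$mature_id[k])
      }
      cuts <- sort(c(lc$start, lc$end,
                     unlist(lapply(mg, function(x) c(x["start"], x["end"])))))
      for (j in seq_len(length(cuts) - 1L)) {
        s <- cuts[j]; e <- cuts[j + 1L]
        inside_mature <- any(vapply(
          mg, function(x) s >= x["start"] && e <= x["end"], logical(1)
        ))
        if (!inside_mature) {
          add(lc, "precursor_nonmature", s, e,
              reg_len = L, anchor = prec_anchor)
        }
      }
      W <- if (scheme$kind == "matched_flank") L else scheme$L
      lab <- if (scheme$kind == "matched_flank") {
        c(up = "up_flank", down = "down_flank")
      } else {
        c(up = "up_kb", down = "down_kb")
      }
      if (lc$strand == "+") {
        add(lc, lab[["up"]], lc$start - W, lc$start)
        add(lc, lab[["down"]], lc$end, lc$end + W)
      } else {
        add(lc, lab[["up"]], lc$end, lc$end + W)
        add(lc, lab[["down"]], lc$start - W, lc$start)
      }
    } else { # distance_bins: bins of width L outward from mature boundaries
      for (k in seq_along(mg)) {
        add(lc, "mature", mg[[k]]["start"], mg[[k]]["end"],
            mature_id = mt$mature_id[k])
        ms <- mg[[k]]["start"]; me <- mg[[k]]["end"]
        for (b in seq_len(scheme$n_bins)) {
          ulab <- paste0("distance_bin_u", b)
          dlab <- paste0("distance_bin_d", b)
          if (lc$strand == "+") {
            add(lc, ulab, ms - b * scheme$L, ms - (b - 1L) * scheme$L)
            add(lc, dlab, me + (b - 1L) * scheme$L, me + b * scheme$L)
          } else {
            add(lc, ulab, me + (b - 1L) * scheme$L, me + b * scheme$L)
            add(lc, dlab, ms - b * scheme$L, ms - (b - 1L) * scheme$L)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      locus_id = character(), label = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      anchor5 = integer(), reg_len = integer(), mature_id = character(),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign variants to labelled regions around precursor loci
#'
#' Intersects variant positions with the labelled regions of every locus
#' under a [region_scheme()]. A variant inside a mature sub-interval is
#' labelled `mature` (mature takes precedence over `precursor_nonmature`);
#' offsets are measured 5'->3' in transcript orientation — from the mature
#' 5' end for `mature`, from the precursor 5' end for
#' `precursor_nonmature`, and from the region 5' end otherwise. The `site`
#' column carries the 1-based position within the mature miRNA for
#' mature-labelled variants.
#'
#' @param study a `mirna_study`, or `NULL` if `loci`/`matures`/`variants`
#'   are given explicitly.
#' @param scheme a [region_scheme()].
#' @param loci,matures,variants explicit tables overriding `study`.
#' @return data frame of assignments: `locus_id`, `region_label`, `offset`,
#'   `site`, `reg_len`, plus the variant columns.
#' @export
assign_regions <- function(study = NULL, scheme = region_scheme("matched_flank"),
                           loci = study$loci, matures = study$matures,
                           variants = study$variants) {
  stopifnot(!is.null(loci), !is.null(variants))
  regions <- build_regions(loci, matures, scheme)
  empty <- data.frame(
    locus_id = character(), region_label = character(), offset = integer(),
    site = integer(), mature_id = character(), reg_len = integer(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), ancestral = character(), pop = character(),
    stringsAsFactors = FALSE
  )
  if (!nrow(regions) || !nrow(variants)) {
    return(empty)
  }
  gr_reg <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  gr_snp <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos + 1L, width = 1L)
  )
  ov <- GenomicRanges::findOverlaps(gr_snp, gr_reg)
  if (!length(ov)) {
    return(empty)
  }
  vi <- S4Vectors::queryHits(ov)
  ri <- S4Vectors::subjectHits(ov)
  reg <- regions[ri, , drop = FALSE]
  v <- variants[vi, , drop = FALSE]
  offset <- ifelse(reg$strand == "+", v$pos - reg$anchor5, reg$anchor5 - v$pos)
  site <- ifelse(reg$label == "mature", offset + 1L, NA_integer_)
  res <- data.frame(
    locus_id = reg$locus_id, region_label = reg$label,
    offset = as.integer(offset), site = as.integer(site),
    mature_id = reg$mature_id, reg_len = reg$reg_len,
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    ancestral = v$ancestral, pop = v$pop, stringsAsFactors = FALSE
  )
  res <- res[order(res$locus_id, res$region_label, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign a single variant relative to a single locus
#'
#' Scalar counterpart of [assign_regions()]; returns `NULL` when the variant
#' overlaps none of the locus's regions.
#'
#' @param locus one-row loci data frame.
#' @param snp one-row variant data frame (`chrom`, `pos`, `ref`, `alt`, ...).
#' @param scheme a [region_scheme()].
#' @param matures mature table for the locus (may be empty).
#' @return one-row assignment data frame or `NULL`.
#' @export
assign_region <- function(locus, snp, scheme = region_scheme("matched_flank"),
                          matures = empty_matures_df()) {
  if (snp$chrom != locus$chrom) {
    return(NULL)
  }
  res <- assign_regions(
    study = NULL, scheme = scheme, loci = locus, matures = matures,
    variants = snp
  )
  if (!nrow(res)) NULL else res
}

#' Site index of a mature-region assignment
#'
#' 1-based position of the variant within the mature miRNA, counted from
#' the mature 5' end.
#'
#' @param assignment one or more rows of an assignment data frame with
#'   `region_label == "mature"`.
#' @return integer vector of site indices.
#' @export
mature_site_of <- function(assignment) {
  if (any(assignment$region_label != "mature")) {
    stop("mature_site_of() requires mature-labelled assignments")
  }
  assignment$offset + 1L
}

#' Flag evolutionarily conserved mature miRNAs
#'
#' A mature is conserved iff some reference mature of equal length matches
#' it with at most `max_mismatches` substitutions (U/T differences are
#' normalized away).
#'
#' @param matures character vector of mature sequences (RNA or DNA).
#' @param reference named character vector of other-species mature
#'   sequences.
#' @param max_mismatches maximum Hamming distance still counted as a match
#'   (default 0: exact matches only).
#' @return logical vector along `matures`.
#' @export
classify_conserved <- function(matures, reference, max_mismatches = 0L) {
  if (!length(reference)) stop("reference mature set is empty")
  if (!length(matures)) return(logical(0))
  norm <- function(x) toupper(chartr("Tt", "Uu", x))
  m <- norm(matures)
  r <- norm(reference)
  r_by_len <- split(r, nchar(r))
  vapply(m, function(x) {
    cand <- r_by_len[[as.character(nchar(x))]]
    if (is.null(cand)) {
      return(FALSE)
    }
    if (max_mismatches == 0L) {
      return(x %in% cand)
    }
    xs <- seq_chars(x)
    any(vapply(cand, function(y) {
      sum(xs != seq_chars(y)) <= max_mismatches
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}
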