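# On-disk representation of a study: genome/transcripts FASTA, loci GFF3
# (pre_miRNA features with child miRNA features) + BED12, variants VCF 4.2
# (INFO keys AA = ancestral allele, POP = population tag), truth tables as
# TSV. Coordinates are 0-based half-open in memory, 1-based in GFF3/VCF.

#' Write a synthetic study to a directory
#'
#' @param study a `mirna_study`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    loci = file.path(dir, "loci.gff3"),
    bed = file.path(dir, "loci.bed"),
    vcf = file.path(dir, "variants.vcf"),
    transcripts = file.path(dir, "transcripts.fa"),
    rates = file.path(dir, "truth_rates.tsv"),
    sites = file.path(dir, "truth_planted_sites.tsv"),
    conserved = file.path(dir, "conserved_reference.fa")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$genome), paths["genome"]
  )
  write_loci_gff3(study$loci, study$matures, paths["loci"])
  write_loci_bed12(study$loci, study$matures, paths["bed"])
  write_variants_vcf(study$variants, nchar(study$genome), paths["vcf"])
  if (!is.null(study$transcripts)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(study$transcripts), paths["transcripts"]
    )
  }
  write.table(
    data.frame(
      label = names(study$truth$region_rates),
      rate = unname(study$truth$region_rates)
    ),
    paths["rates"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  ps <- study$truth$planted_sites
  if (is.null(ps)) {
    ps <- data.frame(
      transcript = character(), start = integer(), mirna = integer(),
      mature_id = character(), mismatches = integer(), wobbles = integer()
    )
  }
  write.table(ps, paths["sites"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(study$truth$conserved_reference)) {
    Biostrings::writeXStringSet(
      Biostrings::RNAStringSet(study$truth$conserved_reference),
      paths["conserved"]
    )
  }
  invisible(paths)
}

write_loci_gff3 <- function(loci, matures, path) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tmirvar\tpre_miRNA\t%d\t%d\t.\t%s\t.\tID=%s;conserved=%s",
      lc$chrom, lc$start + 1L, lc$end, lc$strand, lc$id,
      tolower(lc$conserved)
    )
    mt <- matures[matures$locus_id == lc$id, , drop = FALSE]
    for (k in seq_len(nrow(mt))) {
      g <- mature_genomic(lc, mt$offset[k], mt$length[k])
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\tmirvar\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        lc$chrom, g["start"] + 1L, g["end"], lc$strand,
        mt$mature_id[k], lc$id
      )
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

write_loci_bed12 <- function(loci, matures, path) {
  rows <- vapply(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    mt <- matures[matures$locus_id == lc$id, , drop = FALSE]
    thick <- if (nrow(mt)) {
      mature_genomic(lc, mt$offset[1], mt$length[1])
    } else {
      c(start = lc$start, end = lc$start)
    }
    paste(
      lc$chrom, lc$start, lc$end, lc$id, 0L, lc$strand,
      thick["start"], thick["end"], "0,0,0", 1L,
      lc$end - lc$start, 0L,
      sep = "\t"
    )
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

write_variants_vcf <- function(variants, chrom_lens, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mirvar",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lens), chrom_lens),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=POP,Number=1,Type=String,Description=\"Population tag\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (!is.null(variants) && nrow(variants)) {
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tAA=%s;POP=%s",
      variants$chrom, variants$pos + 1L, variants$ref, variants$alt,
      ifelse(is.na(variants$ancestral), ".", variants$ancestral),
      variants$pop
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genome (or transcriptome) FASTA into named character strings
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), names(x))
}

#' Read precursor loci and mature annotations from GFF3
#'
#' Expects `pre_miRNA` features with `ID` and child `miRNA` features with
#' `Parent`; mature offsets are recomputed from genomic coordinates,
#' strand-aware, and precursor/mature sequences are extracted from the
#' genome.
#'
#' @param path GFF3 file.
#' @param genome named character vector of chromosome sequences.
#' @return list with `loci` and `matures` data frames.
#' @export
read_loci_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_pre <- md$type == "pre_miRNA"
  loci <- data.frame(
    id = as.character(md$ID[is_pre]),
    chrom = as.character(GenomicRanges::seqnames(gr[is_pre])),
    start = GenomicRanges::start(gr[is_pre]) - 1L,
    end = GenomicRanges::end(gr[is_pre]),
    strand = as.character(GenomicRanges::strand(gr[is_pre])),
    stringsAsFactors = FALSE
  )
  cons <- if ("conserved" %in% names(md)) {
    as.character(md$conserved[is_pre]) %in% "true"
  } else {
    rep(FALSE, nrow(loci))
  }
  loci$precursor_seq <- vapply(seq_len(nrow(loci)), function(i) {
    dna <- substr(genome[[loci$chrom[i]]], loci$start[i] + 1L, loci$end[i])
    if (loci$strand[i] == "-") dna <- revcomp_dna(dna)
    dna2rna(dna)
  }, character(1))
  loci$conserved <- cons

  is_mat <- md$type == "miRNA"
  if (!any(is_mat)) {
    return(list(loci = loci, matures = empty_matures_df()))
  }
  parent <- vapply(md$Parent[is_mat], function(p) as.character(p)[1],
                   character(1))
  g_start <- GenomicRanges::start(gr[is_mat]) - 1L
  g_end <- GenomicRanges::end(gr[is_mat])
  li <- match(parent, loci$id)
  offset <- ifelse(loci$strand[li] == "+",
                   g_start - loci$start[li],
                   loci$end[li] - g_end)
  len <- g_end - g_start
  matures <- data.frame(
    locus_id = parent,
    mature_id = as.character(md$ID[is_mat]),
    offset = as.integer(offset), length = as.integer(len),
    stringsAsFactors = FALSE
  )
  matures$seq <- vapply(seq_len(nrow(matures)), function(k) {
    substr(loci$precursor_seq[li[k]], matures$offset[k] + 1L,
           matures$offset[k] + matures$length[k])
  }, character(1))
  list(loci = loci, matures = matures)
}

#' Read variants from a VCF file
#'
#' Positions are converted to 0-based; INFO keys `AA` (ancestral allele)
#' and `POP` (population tag) are parsed when present.
#'
#' @param path VCF file.
#' @return variant data frame (`chrom`, `pos`, `ref`, `alt`, `ancestral`,
#'   `pop`).
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx)) || nrow(fx) == 0L) {
    return(empty_variants_df())
  }
  aa <- suppressWarnings(vcfR::extract.info(vcf, element = "AA"))
  pop <- suppressWarnings(vcfR::extract.info(vcf, element = "POP"))
  data.frame(
    chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]) - 1L,
    ref = fx[, "REF"], alt = fx[, "ALT"],
    ancestral = ifelse(is.na(aa) | aa == ".", NA_character_, aa),
    pop = ifelse(is.na(pop), NA_character_, pop),
    stringsAsFactors = FALSE
  )
}

#' Read a candidate-id list (one id per line)
#'
#' @param path text file; blank lines and `#` comments are skipped.
#' @return character vector of ids.
#' @export
read_candidates <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a study back from a directory written by [write_study()]
#'
#' @param dir directory containing `genome.fa`, `loci.gff3`,
#'   `variants.vcf` and optionally `transcripts.fa`.
#' @return a `mirna_study` (without config or truth unless present).
#' @export
read_study <- function(dir) {
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  lm <- read_loci_gff3(file.path(dir, "loci.gff3"), genome)
  variants <- read_variants_vcf(file.path(dir, "variants.vcf"))
  tx_path <- file.path(dir, "transcripts.fa")
  transcripts <- if (file.exists(tx_path)) read_genome_fasta(tx_path) else NULL
  truth <- NULL
  rates_path <- file.path(dir, "truth_rates.tsv")
  if (file.exists(rates_path)) {
    r <- read.delim(rates_path, stringsAsFactors = FALSE)
    truth <- list(region_rates = setNames(r$rate, r$label))
    cons_path <- file.path(dir, "conserved_reference.fa")
    if (file.exists(cons_path)) {
      cr <- Biostrings::readRNAStringSet(cons_path)
      truth$conserved_reference <- setNames(as.character(cr), names(cr))
    }
  }
  structure(
    list(
      cfg = NULL, genome = genome, loci = lm$loci, matures = lm$matures,
      variants = variants, transcripts = transcripts, truth = truth
    ),
    class = "mirna_study"
  )
}
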