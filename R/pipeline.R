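# End-to-end orchestration: map/assign -> density & spectrum -> fold/ddG
# -> SmiRNAs/targets/deltas -> permutation test, with all intermediate
# tables written as TSV and a structured, auditable run report.

#' Build a pipeline run configuration
#'
#' Either give input file paths (as produced by [write_study()] or from
#' real data) or run the pipeline directly on an in-memory study with
#' [run_pipeline()]. Every threshold lives here; nothing downstream is
#' hard-coded.
#'
#' @param genome,loci,vcf,transcriptome,other_species,candidates input
#'   paths (FASTA / GFF3 / VCF / FASTA / FASTA / id list); `genome`,
#'   `loci` and `vcf` are required for a file-based run, the rest are
#'   optional.
#' @param out_dir output directory for tables and the report.
#' @param scheme region scheme kind for the density stage.
#' @param theta_a,theta_b target-scheme thresholds (see [score_site()]).
#' @param k,n_perm permutation-test draw size and count.
#' @param seed integer seed for the permutation stage.
#' @param energy_params optional path to an energy parameter table
#'   (default: the table shipped with the package).
#' @return object of class `run_config`.
#' @export
run_config <- function(genome = NULL, loci = NULL, vcf = NULL,
                       transcriptome = NULL, other_species = NULL,
                       candidates = NULL, out_dir = NULL,
                       scheme = "matched_flank",
                       theta_a = 4.0, theta_b = 5.0,
                       k = 12L, n_perm = 2000L, seed = 1L,
                       energy_params = NULL) {
  structure(
    list(
      genome = genome, loci = loci, vcf = vcf,
      transcriptome = transcriptome, other_species = other_species,
      candidates = candidates, out_dir = out_dir, scheme = scheme,
      theta_a = theta_a, theta_b = theta_b, k = as.integer(k),
      n_perm = as.integer(n_perm), seed = as.integer(seed),
      energy_params = energy_params
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# tiny FNV-1a hash for the report fingerprint (no external digest dep)
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Stages: region assignment under the configured scheme, per-region
#' density summaries with ANOVA, substitution spectrum, hairpin ddG for
#' every precursor SNP, SmiRNA enumeration and target gain/loss, and (when
#' candidates are supplied) the per-population permutation test. Either
#' pass an in-memory `study` or a file-based `config`; when
#' `config$out_dir` (or `out_dir`) is set, all tables and the report are
#' written there.
#'
#' @param study a `mirna_study` (optional if `config` carries file paths).
#' @param config a [run_config()].
#' @param candidates character vector of candidate locus ids (overrides
#'   `config$candidates`).
#' @param out_dir overrides `config$out_dir`.
#' @param model an [energy_model()]; default built from
#'   `config$energy_params` or the shipped table.
#' @param fold_fun folding backend passed to [ddg_table()].
#' @return object of class `run_report` (see [write_report()]).
#' @export
run_pipeline <- function(study = NULL, config = run_config(),
                         candidates = NULL, out_dir = NULL,
                         model = NULL, fold_fun = fold_mfe) {
  stage <- "load inputs"
  report <- tryCatch({
    if (is.null(study)) {
      stopifnot(!is.null(config$genome), !is.null(config$loci),
                !is.null(config$vcf))
      genome <- read_genome_fasta(config$genome)
      lm <- read_loci_gff3(config$loci, genome)
      study <- structure(
        list(
          cfg = NULL, genome = genome, loci = lm$loci, matures = lm$matures,
          variants = read_variants_vcf(config$vcf),
          transcripts = if (!is.null(config$transcriptome)) {
            read_genome_fasta(config$transcriptome)
          },
          truth = NULL
        ),
        class = "mirna_study"
      )
    }
    if (is.null(candidates) && !is.null(config$candidates)) {
      candidates <- read_candidates(config$candidates)
    }
    if (is.null(out_dir)) out_dir <- config$out_dir
    if (is.null(model)) {
      model <- if (is.null(config$energy_params)) {
        energy_model()
      } else {
        energy_model(config$energy_params)
      }
    }

    stage <- "region assignment"
    scheme <- region_scheme(config$scheme)
    assignments <- assign_regions(study, scheme)

    stage <- "density statistics"
    dens <- density_by_region(assignments, study$loci, study$matures, scheme)
    dens_anova <- density_anova(dens)
    per_site <- if (any(assignments$region_label == "mature") &&
                      nrow(study$matures)) {
      per_site_density(assignments, study$matures)
    }
    len_summary <- length_stratified_summary(assignments, study$matures)

    stage <- "substitution spectrum"
    spectrum <- substitution_spectrum(study$variants)

    stage <- "hairpin energetics"
    ddg <- ddg_table(study$loci, study$variants, model, fold_fun = fold_fun)
    ddg_classes <- table(factor(
      ddg$effect_class,
      levels = c("destabilizing", "stabilizing", "slight", "unchanged")
    ))
    ddg_hist <- if (nrow(ddg)) {
      brk <- seq(floor(min(ddg$ddg)) - 1, ceiling(max(ddg$ddg)) + 1, by = 1)
      h <- hist(ddg$ddg, breaks = brk, plot = FALSE)
      data.frame(bin_lo = h$breaks[-length(h$breaks)],
                 bin_hi = h$breaks[-1], count = h$counts)
    } else {
      data.frame(bin_lo = numeric(), bin_hi = numeric(), count = integer())
    }

    stage <- "target alteration"
    smirnas <- enumerate_smirnas(assignments, study$loci, study$matures)
    targets <- if (!is.null(study$transcripts) && length(study$transcripts)) {
      target_deltas_all(smirnas, study$matures, study$transcripts,
                        config$theta_a, config$theta_b)
    }

    stage <- "permutation test"
    perms <- NULL
    if (!is.null(candidates) && length(candidates)) {
      pops <- unique(study$variants$pop)
      pops <- pops[!is.na(pops)]
      if (!length(pops)) pops <- NA_character_
      perms <- lapply(setNames(pops, paste0("pop_", pops)), function(pp) {
        dpp <- density_by_region(
          assignments, study$loci, study$matures, scheme,
          variants_pop = if (is.na(pp)) NULL else pp
        )
        permutation_test(
          candidates, study$loci$id, dpp,
          region = "precursor", k = config$k, n_perm = config$n_perm,
          seed = config$seed
        )
      })
    }

    stage <- "report"
    region_counts <- table(assignments$region_label)
    structure(
      list(
        counts = list(
          n_loci = nrow(study$loci),
          n_variants = nrow(study$variants),
          snps_per_region = as.list(setNames(
            as.integer(region_counts), names(region_counts)
          )),
          n_mature_snps = sum(assignments$region_label == "mature"),
          n_smirnas = nrow(smirnas),
          ddg_records = nrow(ddg),
          ddg_classes = as.list(setNames(
            as.integer(ddg_classes), names(ddg_classes)
          )),
          n_gained = if (!is.null(targets)) sum(targets$deltas$n_gained) else NA,
          n_lost = if (!is.null(targets)) sum(targets$deltas$n_lost) else NA,
          tstv_ratio = spectrum$tstv_ratio,
          transition_fraction = spectrum$transition_fraction,
          mean_abs_ddg = if (nrow(ddg)) mean(abs(ddg$ddg)) else NA,
          permutation_p = if (!is.null(perms)) {
            lapply(perms, function(x) x$p)
          } else {
            NULL
          }
        ),
        tables = list(
          assignments = assignments, density = dens,
          density_anova = dens_anova, per_site = per_site,
          length_summary = len_summary, spectrum = spectrum, ddg = ddg,
          ddg_hist = ddg_hist, smirnas = smirnas, targets = targets,
          permutations = perms
        ),
        fingerprint = list(
          package = as.character(utils::packageVersion("mirvar")),
          config = fnv1a(config[setdiff(names(config), "out_dir")])
        )
      ),
      class = "run_report"
    )
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  c_ <- x$counts
  cat("<run_report>\n")
  cat("  loci:", c_$n_loci, " variants:", c_$n_variants, "\n")
  cat("  SNPs per region:",
      paste(names(c_$snps_per_region), unlist(c_$snps_per_region),
            sep = "=", collapse = " "), "\n")
  cat("  SmiRNAs:", c_$n_smirnas, " ddG records:", c_$ddg_records, "\n")
  cat("  ddG classes:",
      paste(names(c_$ddg_classes), unlist(c_$ddg_classes),
            sep = "=", collapse = " "), "\n")
  cat("  gained/lost targets:", c_$n_gained, "/", c_$n_lost, "\n")
  cat("  Ts/Tv:", signif(c_$tstv_ratio, 4), "\n")
  if (!is.null(c_$permutation_p)) {
    cat("  permutation p:",
        paste(names(c_$permutation_p), signif(unlist(c_$permutation_p), 4),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Write a run report and its tables to a directory
#'
#' Tab-separated tables for every stage plus `report.json` holding the
#' counts and fingerprint (the auditable summary; histogram bin totals sum
#' to the ddG record count).
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, name) {
    p <- file.path(dir, name)
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  t_ <- report$tables
  paths <- c(
    wt(t_$assignments, "assignments.tsv"),
    wt(t_$density$per_locus, "density_per_locus.tsv"),
    wt(t_$density$summary, "density_summary.tsv"),
    wt(data.frame(type = names(t_$spectrum$directed),
                  count = unname(t_$spectrum$directed)), "spectrum.tsv"),
    wt(t_$ddg, "ddg.tsv"),
    wt(t_$ddg_hist, "ddg_histogram.tsv"),
    wt(t_$smirnas, "smirnas.tsv"),
    wt(t_$length_summary, "length_summary.tsv")
  )
  if (!is.null(t_$per_site)) {
    paths <- c(paths, wt(t_$per_site$per_site, "per_site_density.tsv"))
  }
  if (!is.null(t_$targets)) {
    paths <- c(
      paths,
      wt(t_$targets$wild_hits, "target_hits_wild.tsv"),
      wt(t_$targets$smirna_hits, "target_hits_smirna.tsv"),
      wt(t_$targets$deltas, "target_deltas.tsv")
    )
  }
  if (!is.null(t_$permutations)) {
    perm_df <- do.call(rbind, lapply(names(t_$permutations), function(nm) {
      x <- t_$permutations[[nm]]
      data.frame(population = nm, region = x$region, observed = x$observed,
                 p = x$p, k = x$k, n_perm = x$n_perm, seed = x$seed)
    }))
    null_df <- do.call(rbind, lapply(names(t_$permutations), function(nm) {
      data.frame(population = nm, null_mean = t_$permutations[[nm]]$null)
    }))
    paths <- c(paths, wt(perm_df, "permutation_results.tsv"),
               wt(null_df, "permutation_null.tsv"))
  }
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(counts = report$counts, fingerprint = report$fingerprint),
    json_path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(c(paths, json_path))
}

#' Read back the structured part of a written report
#'
#' @param dir directory written by [write_report()].
#' @return list with `counts` and `fingerprint`.
#' @export
read_report_json <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
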