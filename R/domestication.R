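# Permutation test for low-diversity candidate miRNA sets: is the mean SNP
# density of the candidates lower than that of random same-size sets drawn
# from the remaining miRNAs?

# per-locus densities for one region group (and optionally one population)
locus_densities <- function(table, region, ids = NULL) {
  d <- table$per_locus[table$per_locus$group == region, , drop = FALSE]
  if (!nrow(d)) stop("region group '", region, "' not present in the table")
  v <- setNames(d$density, d$locus_id)
  if (is.null(ids)) {
    return(v)
  }
  missing <- setdiff(ids, names(v))
  if (length(missing)) {
    stop("unknown candidate locus ids: ", paste(missing, collapse = ", "))
  }
  v[ids]
}

#' Mean SNP density of a candidate locus set
#'
#' Arithmetic mean of the candidates' per-locus densities for one region
#' group of a [density_by_region()] table.
#'
#' @param candidates character vector of locus ids.
#' @param table a `density_table`.
#' @param region region group label (e.g. `"precursor"`, `"down_flank"`).
#' @return mean density (SNPs per base).
#' @export
observed_mean_density <- function(candidates, table, region = "precursor") {
  mean(locus_densities(table, region, candidates))
}

#' Permutation test for reduced SNP density in a candidate set
#'
#' Draws `n_perm` random sets of size `k` (without replacement) from the
#' background loci excluding the candidates, recomputes the mean density of
#' each, and reports the one-sided (lower) empirical p with the add-one
#' correction: p = (1 + #\{null <= observed\}) / (n_perm + 1). With
#' `exhaustive = TRUE` every possible draw is enumerated instead of
#' sampled (guarded to <= 1e5 combinations) and `n_perm` is the number of
#' combinations.
#'
#' @param candidates character vector of candidate locus ids.
#' @param background character vector of locus ids to draw from
#'   (candidates are excluded automatically).
#' @param table a `density_table` (compute it from a population-specific
#'   variant subset to test populations separately).
#' @param region region group label.
#' @param k draw size (default 12).
#' @param n_perm number of permutations (default 2000).
#' @param seed integer seed; the null vector is reproducible.
#' @param exhaustive enumerate all combinations instead of sampling.
#' @return object of class `permutation_result`: list(`region`,
#'   `observed`, `null` (n_perm means), `p`, `k`, `n_perm`, `seed`).
#' @export
permutation_test <- function(candidates, background, table,
                             region = "precursor", k = 12L,
                             n_perm = 2000L, seed = 1L,
                             exhaustive = FALSE) {
  observed <- observed_mean_density(candidates, table, region)
  pool_ids <- setdiff(background, candidates)
  if (length(pool_ids) < k) {
    stop(
      "insufficient background: ", length(pool_ids),
      " non-candidate loci for draws of size ", k
    )
  }
  pool <- locus_densities(table, region, pool_ids)
  if (exhaustive) {
    if (choose(length(pool), k) > 1e5) {
      stop("exhaustive enumeration refused: more than 1e5 combinations")
    }
    null <- apply(combn(length(pool), k), 2, function(ix) mean(pool[ix]))
    n_perm <- length(null)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      mean(pool[sample.int(length(pool), k)])
    }, numeric(1))
  }
  p <- (1 + sum(null <= observed)) / (n_perm + 1)
  structure(
    list(
      region = region, observed = observed, null = null, p = p,
      k = as.integer(k), n_perm = as.integer(n_perm), seed = as.integer(seed)
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(
    "<permutation_result>", x$region, ": observed", signif(x$observed, 4),
    "vs null mean", signif(mean(x$null), 4),
    sprintf("(k=%d, %d perms) p = %.4g", x$k, x$n_perm, x$p), "\n"
  )
  invisible(x)
}
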