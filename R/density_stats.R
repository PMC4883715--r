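# SNP density summaries, one-way ANOVA with letter groups, and the
# ancestral-polarized substitution spectrum.

# region groups summarised for each scheme; "precursor" is the full
# precursor including mature bases (mature is also reported separately)
density_groups_for <- function(scheme_kind, labels_present = character(0)) {
  switch(scheme_kind,
    matched_flank = c("precursor", "mature", "up_flank", "down_flank"),
    kb_window = c("precursor", "mature", "up_kb", "down_kb"),
    distance_bins = c("mature", sort(unique(grep(
      "^distance_bin_", labels_present,
      value = TRUE
    ))))
  )
}

#' Per-locus and per-group SNP densities under a region scheme
#'
#' For every locus and region group, density = SNP count / region length
#' (SNPs per base). Loci with zero SNPs contribute density 0 and are part
#' of the group averages. The `precursor` group is the full precursor
#' (mature bases included); `mature` is reported as its own group.
#'
#' @param assignments output of [assign_regions()] under `scheme`.
#' @param loci loci data frame (every locus appears in the output, with or
#'   without SNPs).
#' @param matures mature table (for mature-region lengths).
#' @param scheme the [region_scheme()] the assignments were produced under.
#' @param variants_pop optional population tag; when given, only
#'   assignments with that tag are counted.
#' @return an object of class `density_table`: list with `per_locus` (one
#'   row per locus x group: `locus_id`, `group`, `snp_count`, `bases`,
#'   `density`) and `summary` (per group `n`, `mean`, `se`).
#' @export
density_by_region <- function(assignments, loci, matures,
                              scheme = region_scheme("matched_flank"),
                              variants_pop = NULL) {
  if (!nrow(loci)) stop("empty locus list")
  if (!is.null(variants_pop)) {
    assignments <- assignments[assignments$pop %in% variants_pop, , drop = FALSE]
  }
  groups <- density_groups_for(scheme$kind, assignments$region_label)

  # per-locus region lengths per group
  L <- loci$end - loci$start
  names(L) <- loci$id
  mature_len <- vapply(loci$id, function(id) {
    sum(matures$length[matures$locus_id == id])
  }, numeric(1))

  group_bases <- function(g, id) {
    switch(g,
      precursor = ,
      up_flank = ,
      down_flank = unname(L[id]),
      mature = unname(mature_len[id]),
      up_kb = ,
      down_kb = scheme$L,
      scheme$L # distance bins
    )
  }
  group_count <- function(g, id) {
    a <- assignments[assignments$locus_id == id, , drop = FALSE]
    switch(g,
      precursor = sum(a$region_label %in% c("mature", "precursor_nonmature")),
      sum(a$region_label == g)
    )
  }

  rows <- list()
  for (id in loci$id) {
    for (g in groups) {
      b <- group_bases(g, id)
      if (is.na(b) || b <= 0) next # e.g. locus without annotated mature
      cnt <- group_count(g, id)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = id, group = g, snp_count = cnt, bases = b,
        density = cnt / b, stringsAsFactors = FALSE
      )
    }
  }
  per_locus <- do.call(rbind, rows)
  rownames(per_locus) <- NULL

  summ <- do.call(rbind, lapply(split(per_locus, per_locus$group), function(d) {
    data.frame(
      group = d$group[1], n = nrow(d), mean = mean(d$density),
      se = if (nrow(d) > 1) sd(d$density) / sqrt(nrow(d)) else 0,
      stringsAsFactors = FALSE
    )
  }))
  summ <- summ[match(intersect(groups, summ$group), summ$group), , drop = FALSE]
  rownames(summ) <- NULL

  structure(
    list(per_locus = per_locus, summary = summ, scheme = scheme$kind),
    class = "density_table"
  )
}

#' @export
print.density_table <- function(x, ...) {
  cat("<density_table> scheme:", x$scheme, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA over a density table's region groups
#'
#' @param table a [density_by_region()] result.
#' @param groups which groups to compare (default: all in the table).
#' @param alpha significance level for letter groups.
#' @return an [anova_oneway()] result.
#' @export
density_anova <- function(table, groups = unique(table$per_locus$group),
                          alpha = 0.05) {
  d <- table$per_locus[table$per_locus$group %in% groups, , drop = FALSE]
  anova_oneway(split(d$density, d$group), alpha = alpha)
}

#' Per-site SNP density along mature miRNAs
#'
#' Site `i` (1-based from the mature 5' end) has density
#' (# SNPs at site i) / (# matures of length >= i). Sites are compared by
#' one-way ANOVA over per-mature indicator values, with compact letter
#' groups at `alpha`.
#'
#' @param assignments assignment data frame (mature rows are used).
#' @param matures mature table.
#' @param alpha significance level for the letter display.
#' @return list with `per_site` (site, snp_count, n_matures, density,
#'   letters) and `anova` (the [anova_oneway()] result), class
#'   `per_site_density`.
#' @export
per_site_density <- function(assignments, matures, alpha = 0.05) {
  if (!nrow(matures)) stop("no mature miRNAs")
  a <- assignments[assignments$region_label == "mature", , drop = FALSE]
  max_len <- max(matures$length)
  sites <- seq_len(max_len)
  n_at <- vapply(sites, function(i) sum(matures$length >= i), numeric(1))
  cnt <- vapply(sites, function(i) sum(a$site == i, na.rm = TRUE), numeric(1))

  # per-mature SNP count at each site (0/1 for unique variant sites)
  groups <- lapply(sites, function(i) {
    eligible <- matures$mature_id[matures$length >= i]
    hits <- table(a$mature_id[a$site == i])
    v <- setNames(numeric(length(eligible)), eligible)
    common <- intersect(names(hits), eligible)
    v[common] <- as.numeric(hits[common])
    unname(v)
  })
  names(groups) <- paste0("site", sites)
  aov_res <- anova_oneway(groups, alpha = alpha)

  per_site <- data.frame(
    site = sites, snp_count = cnt, n_matures = n_at,
    density = cnt / n_at,
    letters = unname(aov_res$letters[paste0("site", sites)]),
    stringsAsFactors = FALSE
  )
  structure(list(per_site = per_site, anova = aov_res),
            class = "per_site_density")
}

#' SNP counts, shares and densities stratified by mature length
#'
#' Partitions mature-region SNPs by the length of the host mature miRNA
#' (19-24 nt); the density denominator is the total bases of all matures of
#' that length.
#'
#' @param assignments assignment data frame.
#' @param matures mature table.
#' @return data frame: `length`, `n_matures`, `snp_count`, `share`,
#'   `density`.
#' @export
length_stratified_summary <- function(assignments, matures) {
  a <- assignments[assignments$region_label == "mature", , drop = FALSE]
  host_len <- matures$length[match(a$mature_id, matures$mature_id)]
  lens <- sort(unique(matures$length))
  total <- nrow(a)
  out <- data.frame(
    length = lens,
    n_matures = vapply(lens, function(l) sum(matures$length == l), numeric(1)),
    snp_count = vapply(lens, function(l) sum(host_len == l, na.rm = TRUE),
                       numeric(1)),
    stringsAsFactors = FALSE
  )
  out$share <- if (total > 0) out$snp_count / total else 0
  out$density <- out$snp_count /
    vapply(lens, function(l) sum(matures$length[matures$length == l]),
           numeric(1))
  out
}

# Welch two-sample t-test p-value with degenerate-variance handling:
# both groups constant -> p = 1 if equal means else 0.
welch_p <- function(x, y) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0)) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                   vy^2 / (length(y)^2 * (length(y) - 1)))
  2 * pt(-abs(t), df)
}

# compact letter display by insert-and-absorb over a logical "significantly
# different" matrix; guarantees significant pairs never share a letter and
# non-significant pairs share at least one
letter_groups <- function(signif_mat) {
  g <- rownames(signif_mat)
  sets <- list(g)
  pairs <- which(signif_mat & upper.tri(signif_mat), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- g[pairs[r, 1]]
    b <- g[pairs[r, 2]]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets that are subsets of another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- unique(new_sets[keep])
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  # order sets by the first member's position for stable letter naming
  ord <- order(vapply(sets, function(s) min(match(s, g)), numeric(1)))
  sets <- sets[ord]
  out <- setNames(rep("", length(g)), g)
  for (k in seq_along(sets)) {
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  }
  out
}

#' Classical one-way ANOVA with compact letter display
#'
#' F and p from the classical one-way analysis of variance; letter groups
#' from all pairwise Welch t-tests, Holm-corrected, at level `alpha`.
#' Groups sharing a letter are not significantly different pairwise.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2
#'   for a meaningful F; degenerate all-identical input returns F = 0,
#'   p = 1).
#' @param alpha significance level.
#' @return object of class `anova_result`: list(F, p, letters, pairwise_p).
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  stopifnot(length(groups) >= 2L)
  vals <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(vals)) == 1L) {
    letters_out <- setNames(rep("a", length(groups)), names(groups))
    return(structure(
      list(F = 0, p = 1, letters = letters_out,
           pairwise_p = matrix(1, length(groups), length(groups),
                               dimnames = list(names(groups), names(groups)))),
      class = "anova_result"
    ))
  }
  fit <- anova(aov(vals ~ lab))
  Fv <- fit[["F value"]][1]
  pv <- fit[["Pr(>F)"]][1]

  k <- length(groups)
  pw <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  idx <- which(upper.tri(pw), arr.ind = TRUE)
  praw <- apply(idx, 1L, function(ij) welch_p(groups[[ij[1]]], groups[[ij[2]]]))
  padj <- p.adjust(praw, method = "holm")
  for (r in seq_len(nrow(idx))) {
    pw[idx[r, 1], idx[r, 2]] <- padj[r]
    pw[idx[r, 2], idx[r, 1]] <- padj[r]
  }
  diag(pw) <- 1
  letters_out <- letter_groups(pw < alpha)

  structure(
    list(F = Fv, p = pv, letters = letters_out, pairwise_p = pw),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> F =", signif(x$F, 5), ", p =", signif(x$p, 5), "\n")
  cat("letters:", paste(names(x$letters), x$letters, sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

#' Ancestral-polarized substitution spectrum and Ts/Tv ratio
#'
#' A variant is polarized when its ancestral allele equals the reference or
#' one of the alternates; its direction is ancestral -> derived for every
#' non-ancestral allele. Unpolarized variants (unknown or inconsistent
#' ancestral state) contribute to the collapsed 6-type counts and to the
#' transition:transversion ratio only. Directions are reported on the
#' genome plus strand.
#'
#' @param snps variant data frame (`ref`, `alt`, `ancestral`).
#' @return object of class `spectrum_summary`: `directed` (12 counts,
#'   e.g. `"C>T"`), `undirected` (6 counts, e.g. `"C/T"`, unpolarized
#'   variants), `n_polarized`, `n_unpolarized`, `transitions`,
#'   `transversions`, `transition_fraction`, `tstv_ratio`.
#' @export
substitution_spectrum <- function(snps) {
  bases <- c("A", "C", "G", "T")
  directed_names <- as.vector(outer(bases, bases, function(a, b) {
    paste0(a, ">", b)
  }))
  directed_names <- directed_names[substr(directed_names, 1, 1) !=
                                     substr(directed_names, 3, 3)]
  directed <- setNames(integer(length(directed_names)), directed_names)
  undirected_names <- apply(combn(bases, 2), 2, paste, collapse = "/")
  undirected <- setNames(integer(length(undirected_names)), undirected_names)

  n_pol <- 0L
  n_unpol <- 0L
  for (i in seq_len(nrow(snps))) {
    alts <- strsplit(snps$alt[i], ",", fixed = TRUE)[[1]]
    alleles <- c(snps$ref[i], alts)
    anc <- snps$ancestral[i]
    if (!is.na(anc) && anc %in% alleles) {
      n_pol <- n_pol + 1L
      for (d in setdiff(alleles, anc)) {
        key <- paste0(anc, ">", d)
        directed[key] <- directed[key] + 1L
      }
    } else {
      n_unpol <- n_unpol + 1L
      for (a in alts) {
        key <- paste(sort(c(snps$ref[i], a)), collapse = "/")
        undirected[key] <- undirected[key] + 1L
      }
    }
  }
  dir_from <- substr(names(directed), 1, 1)
  dir_to <- substr(names(directed), 3, 3)
  tr_dir <- sum(directed[is_transition(dir_from, dir_to)])
  tv_dir <- sum(directed) - tr_dir
  tr_und <- sum(undirected[c("A/G", "C/T")])
  tv_und <- sum(undirected) - tr_und
  tr <- tr_dir + tr_und
  tv <- tv_dir + tv_und

  structure(
    list(
      directed = directed, undirected = undirected,
      n_polarized = n_pol, n_unpolarized = n_unpol,
      transitions = tr, transversions = tv,
      transition_fraction = if (tr + tv > 0) tr / (tr + tv) else NA_real_,
      tstv_ratio = if (tv > 0) tr / tv else NA_real_
    ),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(
    "<spectrum_summary>", x$n_polarized, "polarized +", x$n_unpolarized,
    "unpolarized; Ts/Tv =", signif(x$tstv_ratio, 4),
    "( transition fraction", signif(x$transition_fraction, 4), ")\n"
  )
  invisible(x)
}
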