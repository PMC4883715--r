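# Folding: dynamic-programming MFE (C++ backend), an independent
# exhaustive-enumeration folder used as a test oracle, a dot-bracket
# structure scorer, and the wild-vs-SNP ddG machinery.

normalize_rna <- function(seq) {
  s <- toupper(chartr("Tt", "Uu", seq))
  if (grepl("[^ACGU]", s)) {
    stop("sequence contains characters outside {A,C,G,U} (after T->U)")
  }
  s
}

rna_codes <- function(s) {
  match(seq_chars(s), c("A", "C", "G", "U")) - 1L
}

new_fold_result <- function(seq, structure, mfe_cents, n_pairs) {
  structure(
    list(seq = seq, structure = structure, mfe = mfe_cents / 100,
         n_pairs = n_pairs),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, " (", sprintf("%.2f", x$mfe), ")\n", sep = "")
  invisible(x)
}

#' Minimum-free-energy fold of an RNA sequence
#'
#' Dynamic-programming minimum over all pseudoknot-free structures under
#' the package's simplified nearest-neighbor [energy_model()]. Among
#' co-optimal structures the one with more base pairs is preferred;
#' remaining ties are resolved by a fixed deterministic traceback order,
#' so the result is reproducible. The MFE is never positive (the empty
#' structure scores 0).
#'
#' @param seq RNA string (ACGU; T is accepted and read as U), length
#'   <= 2000.
#' @param model an [energy_model()].
#' @return object of class `fold_result`: `seq`, `structure` (dot-bracket),
#'   `mfe` (kcal/mol), `n_pairs`.
#' @examples
#' m <- energy_model()
#' fold_mfe("GGGGAAAACCCC", m)
#' @export
fold_mfe <- function(seq, model = energy_model()) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  stopifnot(n >= 1L, n <= 2000L)
  par <- model_as_cents(model, n)
  res <- .fold_mfe_cpp(
    rna_codes(s), par$stack, par$hairpin, par$bulge, par$internal,
    par$ml, par$min_loop, par$max_interior
  )
  new_fold_result(s, res$structure, res$mfe_cents, res$pairs)
}

# parse a dot-bracket string into a 1-based pair table (0 = unpaired)
pair_table <- function(db) {
  ch <- seq_chars(db)
  pt <- integer(length(ch))
  stk <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stk <- c(stk, i)
    } else if (ch[i] == ")") {
      if (!length(stk)) stop("unbalanced dot-bracket string")
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid character in dot-bracket string: ", ch[i])
    }
  }
  if (length(stk)) stop("unbalanced dot-bracket string")
  pt
}

#' Energy of a fixed secondary structure
#'
#' Scores a dot-bracket structure by standard loop decomposition (stacks,
#' hairpin/bulge/internal loops, affine multiloops; the exterior loop is
#' free) under the same parameters as [fold_mfe()], but via an independent
#' code path. Used both to verify reported folds and as the scoring half
#' of the exhaustive oracle.
#'
#' @param seq RNA string.
#' @param db dot-bracket structure of the same length.
#' @param model an [energy_model()].
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, db, model = energy_model()) {
  s <- normalize_rna(seq)
  stopifnot(nchar(s) == nchar(db))
  structure_energy_cents(seq_chars(s), pair_table(db), model) / 100
}

structure_energy_cents <- function(ch, pt, model) {
  n <- length(ch)
  stk <- matrix(as.integer(round(100 * model$stack)), 6, 6)
  ml <- as.integer(round(100 * model$ml))
  pen <- function(tab, size) loop_pen_cents(tab, model$lxc, size)
  total <- 0L
  pairs_i <- which(pt > seq_len(n)) # opening positions
  for (i in pairs_i) {
    j <- pt[i]
    pc_out <- pair_code(ch[i], ch[j])
    if (pc_out == 0L) stop("disallowed pair ", ch[i], ":", ch[j])
    if (j - i - 1L < model$min_loop) stop("pair violates minimum loop size")
    # children: helices directly enclosed by (i, j)
    children <- integer(0)
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        children <- c(children, k)
        k <- pt[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (length(children) == 0L) {
      total <- total + pen(model$hairpin, j - i - 1L)
    } else if (length(children) == 1L) {
      k <- children[1]
      l <- pt[k]
      n1 <- k - i - 1L
      n2 <- j - l - 1L
      if (n1 == 0L && n2 == 0L) {
        pc_in <- pair_code(ch[k], ch[l])
        total <- total + stk[pc_out, pc_in]
      } else if (n1 == 0L || n2 == 0L) {
        total <- total + pen(model$bulge, n1 + n2)
      } else {
        total <- total + pen(model$internal, n1 + n2)
      }
    } else {
      total <- total + ml[1] + ml[2] * (length(children) + 1L) +
        ml[3] * unpaired
    }
  }
  total
}

#' Exhaustive-enumeration fold (test oracle)
#'
#' Enumerates every pseudoknot-free structure satisfying the pairing and
#' minimum-loop constraints, scores each with [structure_energy()], and
#' returns the minimum (ties: more pairs, then lexicographically smallest
#' dot-bracket). Exponential in length; refused above 18 nt.
#'
#' @inheritParams fold_mfe
#' @return a `fold_result`.
#' @export
fold_exhaustive <- function(seq, model = energy_model()) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  if (n > 18L) stop("fold_exhaustive is limited to sequences of <= 18 nt")
  ch <- seq_chars(s)
  h <- model$min_loop

  memo <- new.env(parent = emptyenv())
  # all structures of [i..j] as lists of 2-column pair matrices
  enum <- function(i, j) {
    if (i > j) {
      return(list(matrix(integer(0), ncol = 2)))
    }
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    out <- enum(i + 1L, j) # i unpaired
    l0 <- i + h + 1L
    if (l0 <= j) {
      for (l in l0:j) {
        if (pair_code(ch[i], ch[l]) == 0L) next
        left <- enum(i + 1L, l - 1L)
        right <- enum(l + 1L, j)
        for (a in left) {
          for (b in right) {
            out[[length(out) + 1L]] <- rbind(a, c(i, l), b)
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }

  best <- NULL
  for (prs in enum(1L, n)) {
    pt <- integer(n)
    if (nrow(prs)) {
      pt[prs[, 1]] <- prs[, 2]
      pt[prs[, 2]] <- prs[, 1]
    }
    e <- structure_energy_cents(ch, pt, model)
    np <- nrow(prs)
    db <- rep(".", n)
    db[prs[, 1]] <- "("
    db[prs[, 2]] <- ")"
    db <- paste(db, collapse = "")
    if (is.null(best) || e < best$e ||
        (e == best$e && (np > best$np ||
                           (np == best$np && db < best$db)))) {
      best <- list(e = e, np = np, db = db)
    }
  }
  new_fold_result(s, best$db, best$e, best$np)
}

#' Structural context of a precursor position
#'
#' `"stem"` if the position is paired in the wild-type MFE structure,
#' `"loop"` otherwise.
#'
#' @param wild_fold a `fold_result` for the wild-type precursor.
#' @param precursor_offset 0-based offset(s) within the precursor.
#' @return character vector of `"stem"`/`"loop"`.
#' @export
snp_context <- function(wild_fold, precursor_offset) {
  pt <- pair_table(wild_fold$structure)
  stopifnot(all(precursor_offset >= 0L),
            all(precursor_offset < length(pt)))
  ifelse(pt[precursor_offset + 1L] > 0L, "stem", "loop")
}

#' Classify a free-energy change
#'
#' Sign convention: positive ddG means the SNP-type hairpin is less stable
#' than the wild type. Bins: `|ddG| <= 0.05` unchanged; `< 0.3` slight;
#' `>= 0.3` destabilizing; `<= -0.3` stabilizing.
#'
#' @param ddg numeric vector of free-energy changes (kcal/mol).
#' @return character vector of effect classes.
#' @export
classify_ddg <- function(ddg) {
  ifelse(abs(ddg) <= 0.05, "unchanged",
    ifelse(abs(ddg) < 0.3, "slight",
      ifelse(ddg >= 0.3, "destabilizing", "stabilizing")
    )
  )
}

#' Free-energy change of a precursor SNP
#'
#' Builds the SNP-type precursor strand-aware (the allele is complemented
#' for minus-strand loci), refolds, and reports
#' ddG = MFE(SNP-type) - MFE(wild-type) with the structural context of the
#' site in the wild-type fold. One record per alternate allele; an
#' alternate that maps onto the existing transcript base gives ddG = 0
#' exactly.
#'
#' @param locus one-row loci data frame.
#' @param snp one-row variant data frame overlapping the precursor.
#' @param model an [energy_model()].
#' @param fold_fun folding backend, `function(seq, model) -> fold_result`;
#'   defaults to the internal [fold_mfe()].
#' @param wild_fold optional precomputed wild-type fold (saves refolding
#'   when processing many SNPs per locus).
#' @return data frame with one row per alt allele: `locus_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `offset`, `context`, `ddg`, `effect_class`.
#' @export
delta_delta_g <- function(locus, snp, model = energy_model(),
                          fold_fun = fold_mfe, wild_fold = NULL) {
  if (snp$chrom != locus$chrom || snp$pos < locus$start ||
      snp$pos >= locus$end) {
    stop("SNP does not overlap the precursor")
  }
  off <- if (locus$strand == "+") {
    snp$pos - locus$start
  } else {
    locus$end - 1L - snp$pos
  }
  wild <- normalize_rna(locus$precursor_seq)
  if (is.null(wild_fold)) wild_fold <- fold_fun(wild, model)
  ctx <- snp_context(wild_fold, off)
  alts <- strsplit(snp$alt, ",", fixed = TRUE)[[1]]
  rows <- lapply(alts, function(a) {
    base_t <- dna2rna(if (locus$strand == "+") a else comp_base(a))
    if (substr(wild, off + 1L, off + 1L) == base_t) {
      ddg <- 0
    } else {
      mut <- wild
      substr(mut, off + 1L, off + 1L) <- base_t
      mut_fold <- fold_fun(mut, model)
      ddg <- round(mut_fold$mfe - wild_fold$mfe, 10)
    }
    data.frame(
      locus_id = locus$id, chrom = snp$chrom, pos = snp$pos, ref = snp$ref,
      alt = a, offset = off, context = ctx, ddg = ddg,
      effect_class = classify_ddg(ddg), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' ddG records for every precursor SNP in a study
#'
#' Folds each wild-type precursor once, then computes [delta_delta_g()]
#' for every overlapping variant and alternate allele.
#'
#' @param loci loci data frame.
#' @param variants variant data frame.
#' @param model an [energy_model()].
#' @param fold_fun folding backend (see [delta_delta_g()]).
#' @return data frame of ddG records (possibly zero rows).
#' @export
ddg_table <- function(loci, variants, model = energy_model(),
                      fold_fun = fold_mfe) {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    v <- variants[variants$chrom == lc$chrom & variants$pos >= lc$start &
                    variants$pos < lc$end, , drop = FALSE]
    if (!nrow(v)) next
    wf <- fold_fun(normalize_rna(lc$precursor_seq), model)
    for (k in seq_len(nrow(v))) {
      out[[length(out) + 1L]] <- delta_delta_g(
        lc, v[k, ], model, fold_fun = fold_fun, wild_fold = wf
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      locus_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), offset = integer(),
      context = character(), ddg = numeric(), effect_class = character(),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write folds in Vienna format
#'
#' Three lines per record: `>name`, sequence, dot-bracket with the energy
#' in parentheses.
#'
#' @param folds named list of `fold_result` objects.
#' @param file output path.
#' @export
write_vienna <- function(folds, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(folds)) {
    f <- folds[[nm]]
    writeLines(c(
      paste0(">", nm), f$seq,
      sprintf("%s (%.2f)", f$structure, f$mfe)
    ), con)
  }
  invisible(file)
}
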