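# Simplified nearest-neighbor energy model for RNA hairpin folding.
# Parameters live in a plain-text table (see inst/extdata) so they can be
# inspected and edited; all internal arithmetic uses integer centi-kcal/mol
# so optimum comparisons are exact.

#' Load the folding energy model
#'
#' Reads a long-format parameter table (`section`, `key1`, `key2`, `value`
#' in kcal/mol): pairwise stacking energies over the six allowed pairs
#' (AU, UA, CG, GC, GU, UG), hairpin/bulge/internal loop penalties by loop
#' size (extrapolated logarithmically beyond the table), and affine
#' multiloop constants. This is a deliberately simple model — it captures
#' the qualitative energetics of hairpin stems and loops and is used
#' self-consistently for wild-type vs SNP-type comparisons; it does not
#' reproduce any external folding program's numbers.
#'
#' @param file parameter file; default is the table shipped with the
#'   package.
#' @return object of class `energy_model`: list with `pairs`, `stack`
#'   (6x6 matrix), `hairpin`, `bulge`, `internal` (penalty vectors by
#'   size), `ml` (close/branch/unpaired), `lxc`, `min_loop`,
#'   `max_interior`.
#' @export
energy_model <- function(file = system.file("extdata", "rna_energy_params.tsv",
                                            package = "mirvar")) {
  tab <- read.delim(file, comment.char = "#", header = FALSE,
                    col.names = c("section", "key1", "key2", "value"),
                    stringsAsFactors = FALSE)
  pairs <- c("AU", "CG", "GC", "UA", "GU", "UG")
  st <- tab[tab$section == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  for (r in seq_len(nrow(st))) stack[st$key1[r], st$key2[r]] <- st$value[r]
  grab <- function(section) {
    s <- tab[tab$section == section, ]
    setNames(s$value, s$key1)
  }
  hairpin <- grab("hairpin")
  bulge <- grab("bulge")
  internal <- grab("internal")
  ml <- grab("multiloop")
  misc <- grab("misc")

  model <- structure(
    list(
      pairs = pairs, stack = stack,
      hairpin = hairpin, bulge = bulge, internal = internal,
      ml = c(close = unname(ml["close"]), branch = unname(ml["branch"]),
             unpaired = unname(ml["unpaired"])),
      lxc = unname(misc["lxc"]),
      min_loop = as.integer(misc["min_loop"]),
      max_interior = as.integer(misc["max_interior"])
    ),
    class = "energy_model"
  )
  validate_energy_model(model)
  model
}

validate_energy_model <- function(m) {
  if (any(is.na(m$stack))) stop("stacking table incomplete")
  wc <- c("AU", "UA", "CG", "GC")
  if (any(m$stack[wc, wc] > 0)) {
    stop("Watson-Crick-on-Watson-Crick stacks must be <= 0")
  }
  if (any(c(m$hairpin, m$bulge, m$internal, m$ml) < 0)) {
    stop("loop penalties and multiloop constants must be >= 0")
  }
  stopifnot(m$min_loop >= 3L, m$max_interior >= 2L, m$lxc > 0)
  invisible(m)
}

# pair code 1..6 for two RNA bases, 0 if not pairable
pair_code <- function(a, b) {
  key <- paste0(a, b)
  codes <- c(AU = 1L, CG = 2L, GC = 3L, UA = 4L, GU = 5L, UG = 6L)
  out <- unname(codes[key])
  out[is.na(out)] <- 0L
  out
}

# integer centi-kcal loop penalties with logarithmic extrapolation past the
# table end; shared by the R scorer, exhaustive folder and (via exported
# integer tables) the C++ DP
loop_pen_cents <- function(table, lxc, size) {
  sizes <- as.integer(names(table))
  mx <- max(sizes)
  vapply(size, function(s) {
    if (s <= 0L) return(1000000L)
    if (s <= mx) {
      v <- table[as.character(s)]
      # below the table minimum (e.g. hairpin < 3): effectively forbidden
      if (is.na(v)) return(1000000L)
      as.integer(round(100 * v))
    } else {
      as.integer(round(100 * (table[as.character(mx)] + lxc * log(s / mx))))
    }
  }, integer(1))
}

# pack the model into integer vectors for the C++ DP: penalties are
# pre-expanded up to length n so the DP never extrapolates itself
model_as_cents <- function(model, n) {
  sz <- max(n, 31L)
  list(
    stack = matrix(as.integer(round(100 * model$stack)), 6, 6),
    hairpin = loop_pen_cents(model$hairpin, model$lxc, seq_len(sz)),
    bulge = loop_pen_cents(model$bulge, model$lxc, seq_len(sz)),
    internal = loop_pen_cents(model$internal, model$lxc, seq_len(sz)),
    ml = as.integer(round(100 * model$ml)),
    min_loop = model$min_loop,
    max_interior = model$max_interior
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> 6-pair stacking; min loop", x$min_loop,
      "; interior cap", x$max_interior, "\n")
  invisible(x)
}
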