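# Small sequence helpers shared across modules. Sequences are plain character
# strings; DNA uses ACGT, RNA uses ACGU, always written 5'->3'.

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (ACGT).
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Reverse complement of an RNA string
#'
#' @param x character vector of RNA strings (ACGU).
#' @return character vector of reverse complements.
#' @export
revcomp_rna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

#' DNA to RNA (T -> U)
#' @param x character vector of DNA strings.
#' @return RNA strings.
#' @export
dna2rna <- function(x) chartr("Tt", "Uu", x)

#' RNA to DNA (U -> T)
#' @param x character vector of RNA strings.
#' @return DNA strings.
#' @export
rna2dna <- function(x) chartr("Uu", "Tt", x)

# complement of single DNA bases, vectorized over a character vector of bases
comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

# split a string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# random DNA string(s) of given lengths, uniform base composition by default
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# transition partner of each DNA base (A<->G, C<->T)
transition_of <- function(b) unname(c(A = "G", G = "A", C = "T", T = "C")[b])

# the two transversion partners of a DNA base
transversions_of <- function(b) {
  setdiff(c("A", "C", "G", "T"), c(b, transition_of(b)))
}

#' Is a substitution a transition?
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' substitutions; everything else is a transversion.
#'
#' @param from,to character vectors of single DNA bases.
#' @return logical vector.
#' @export
is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}
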