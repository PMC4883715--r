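---
title: "mirvar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirvar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mirvar` analyses single nucleotide polymorphisms (SNPs) in and around
microRNA precursor loci: where variants fall (mature miRNA, the rest of the
precursor, matched flanks, fixed windows, distance bins), how dense they are
per region, what the ancestral-polarized substitution spectrum looks like,
how a precursor SNP changes hairpin folding free energy, whether a mature
SNP gains or loses predicted targets, and whether a candidate miRNA set
(for example domestication-associated loci) is unusually SNP-poor. Every
stage runs on fully synthetic inputs produced by the package's own
generator, so the whole pipeline is testable without any external download.

```{r, eval = FALSE}
library(mirvar)
cfg <- sim_config(seed = 1, n_loci = 20)
study <- simulate_study(cfg)
report <- run_pipeline(study, run_config(k = 3, n_perm = 500),
                       candidates = study$loci$id[1:3])
report
```

# Coordinates and strand conventions

Internally all genomic intervals are 0-based half-open; GFF3 and VCF use
1-based coordinates and are converted at the I/O boundary. Region labels
and offsets are always reported in *transcript* orientation: "up" means the
5' side of the transcribed precursor, which is the genomic right side for a
minus-strand locus, and offsets count 5' to 3' from the region's 5' edge.
For the `mature` label the offset counts from the mature 5' end (so `site =
offset + 1`); for `precursor_nonmature` it counts from the precursor 5' end,
which makes it directly comparable with mature annotations. A deliberate
consequence is strand symmetry: reverse-complementing the genome, mirroring
all coordinates and flipping strands leaves every (label, offset)
assignment unchanged, and the test suite checks exactly that transform.

Precursor placement uses exact substring search on both strands
(`map_precursor_exact()`). Only perfect placements are useful downstream —
a locus must correspond letter-for-letter to the genome for variant
projection to be meaningful — so a heuristic aligner would add complexity
without adding placements. Multi-mapping precursors keep every placement as
a separate locus copy and contribute once per placement to density
statistics; the output flags them by the `.n` id suffix.

# Region schemes

Three schemes are provided.

* `matched_flank`: each flank has the same length as its own precursor, so
  the precursor and flank densities are directly comparable per locus.
* `kb_window`: fixed windows (default 1000 bases) outward from the
  precursor boundaries, reported alongside (not excluding) the matched
  flanks.
* `distance_bins`: consecutive bins of configurable width (default 150
  bases, on the order of a typical precursor length) outward from the
  mature miRNA boundaries, labelled `distance_bin_u1..`/`distance_bin_d1..`
  for the upstream/downstream direction.

Density for the "precursor" group is computed over the *full* precursor,
mature bases included, while the mature region is also reported as its own
group; a mature-region variant therefore appears in both groups, and the
disjoint partition used for bookkeeping checks is
mature / precursor-minus-mature / flanks.

Per-locus density (count divided by region length), not pooled
counts-over-pooled-bases, is the averaging unit; group summaries report the
mean ± standard error across loci, and loci with zero variants enter the
average with density 0. This choice makes the group mean an unweighted
average over loci — the natural unit when loci differ in length — and it is
what the permutation test resamples.

# ANOVA and letter groups

Group comparisons use the classical one-way F test. The compact letter
display is built from all pairwise Welch t-tests, Holm-adjusted, by the
insert-and-absorb algorithm; the construction guarantees that two groups
sharing a letter are never significantly different and that two groups not
significantly different share at least one letter. (A strict "share iff not
significant" rule is not achievable in general because significance is not
transitive.) Degenerate input — all observations identical — returns F = 0,
p = 1 by convention, and pairwise tests where both groups have zero
variance fall back to comparing means exactly.

# Substitution spectrum

A variant is polarized when its ancestral allele matches the reference or
one of the alternates; its direction is ancestral to derived, one count per
derived allele (multi-allelic records therefore contribute one density
count but several spectrum counts). Variants with unknown or inconsistent
ancestral states fall back to unpolarized 6-type counts and still
contribute to the transition:transversion ratio. Substitutions are reported
on the genome plus strand; the aggregate Ts/Tv ratio is strand-symmetric,
so this convention does not bias it.

# Hairpin energetics

Folding uses an internal simplified nearest-neighbor model: stacking
energies over the six allowed pairs (AU, UA, CG, GC, GU, UG), hairpin,
bulge and internal-loop penalties by loop size with logarithmic
extrapolation beyond size 30, interior loops capped at 30 unpaired bases,
affine multiloops (close 3.4, branch 0.4, unpaired 0.1 kcal/mol), minimum
hairpin loop 3, and no dangles or terminal penalties. The parameters ship
as an editable plain-text table (`inst/extdata/rna_energy_params.tsv`),
approximate published stacking values, and are used *self-consistently*:
every wild-versus-SNP comparison folds both sequences under the same model,
so the ΔΔG sign and classification do not depend on matching any external
program's absolute energies. Users who want a different energy backend can
pass any `function(seq, model) -> fold_result` as `fold_fun` to
`delta_delta_g()`/`ddg_table()`.

The minimum-free-energy fold is a Zuker-style dynamic program over
pseudoknot-free structures, implemented in C++ with all energies as integer
hundredths of kcal/mol, so optima and ties are exact. Among co-optimal
structures the one with more base pairs wins; remaining ties are resolved
by a fixed traceback preference order (hairpin, then interior with the
leftmost inner pair, then multiloop), which makes results deterministic.
The independent oracle, `fold_exhaustive()`, enumerates every valid
structure explicitly (refused above 18 nt) and scores each with
`structure_energy()`, a separate loop-decomposition scorer that is also
used to verify that every reported fold's energy equals its reported MFE.

ΔΔG is defined as MFE(SNP-type) − MFE(wild-type): positive values mean the
variant destabilizes the hairpin. Classification bins: `|ΔΔG| ≤ 0.05`
unchanged, `< 0.3` slight, `≥ 0.3` destabilizing, `≤ −0.3` stabilizing.
The 0.05 threshold separates exact zeros (e.g. a variant whose allele maps
onto the existing transcript base) from genuinely small changes at the 0.1
kcal/mol granularity of the slight band; it is a package convention, chosen
once. The structural context of a variant (`stem`/`loop`) is read off the
wild-type MFE structure: paired means stem.

# Target prediction

Plant miRNA targets are near-perfectly complementary, so scanning is
ungapped: every window of every transcript is compared against the reverse
complement of the miRNA. Two independent rule sets are applied and only
sites accepted by **both** count ("consensus"):

* **Scheme A** (weighted penalty): mismatch 1.0, G:U wobble 0.5, both
  doubled at miRNA positions 2–13; accept when the penalty is ≤ 4.0.
* **Scheme B** (seed and cleavage site): at most one defect (mismatch or
  wobble) at positions 2–8, no mismatch at positions 10–11, unweighted
  penalty ≤ 5.0.

These are explicit, documented stand-ins for the two published plant target
predictors whose consensus defines the gain/loss computation; thresholds
and windows are configuration defaults, not claims about the original
tools. Gain and loss are evaluated at transcript-id granularity: a
transcript is *gained* when the SNP-type miRNA hits it under the consensus
and the wild type does not, *lost* in the opposite case. Overlapping
candidate windows on one transcript collapse to the best scheme-A score
(ties to the smallest start) for set-level comparisons.

SNP-type mature miRNAs (SmiRNAs) are enumerated one per (mature, SNP,
alternate allele), with the allele complemented into transcript space for
minus-strand loci; an alternate that maps onto the existing transcript base
is skipped, so every SmiRNA differs from its wild type at exactly one site.

# Permutation test for candidate sets

Whether a candidate set (e.g. putative domestication-related miRNAs) is
SNP-poor is tested by drawing `n_perm` random same-size sets from the
non-candidate loci and comparing mean per-locus densities, one-sided
(lower), with the add-one empirical p:
p = (1 + #{null ≤ observed}) / (n_perm + 1). Candidates are excluded from
the null pool — the question is "fewer SNPs than *other* miRNAs". Defaults
are k = 12 and n_perm = 2000. An exhaustive mode enumerates all
combinations when their number is small, which makes tiny cases exactly
checkable. Populations are analysed independently by computing the density
table from each population's variant subset.

A calibration note: uniformity of the empirical p holds when candidate
densities are drawn from the same *distribution* as the background. If one
instead repeatedly designates a subset of one fixed, finite locus panel as
"candidates", the exclusion of the candidates from the null pool induces a
finite-population correlation and the p distribution is visibly
non-uniform; the calibration tests therefore redraw both panels each
replicate.

# The synthetic-data generator

The generator emulates the structure of a plant miRNA-SNP study.

* **Loci**: each precursor is 5' arm + terminal loop (4–8 nt) + the reverse
  complement of the arm, with independent per-position stem mismatches at
  rate 0.05; lengths 80–160 nt; one mature miRNA of 19–24 nt (weights
  follow the empirical rice mature-length mix: roughly half 21 nt, then 22
  and 24 nt) annotated in one arm. Loci are placed in evenly spaced slots
  with random jitter, at least 2 kb apart, half on each strand; slotted
  placement guarantees the separation (so matched flanks and 1-kb windows
  never collide) without rejection sampling.
* **Variants**: every base carries an independent per-base variant
  probability by region class (defaults: mature 0.012, precursor 0.02,
  flank 0.005, background 0.002 per base — precursor-enriched, mature below
  precursor, flanks low). The alternate allele is a transition with
  probability odds/(odds+1) (default odds 2.46), the two transversions
  splitting the remainder equally; the ancestral allele equals the
  reference unless deliberately scrambled, and each variant gets a
  population tag drawn uniformly. Sampling draws a Binomial(B, r) count and
  then a uniform subset of positions, which is distributionally identical
  to per-base coin flips and much faster.
* **Transcripts**: random sequences with, on request, embedded windows
  equal to the reverse complement of a chosen mature carrying an exact
  number of mismatches and G:U wobbles at recorded positions.

The planted truth (rates, Ts:Tv odds, conserved reference set, site
registry) travels with the study so that downstream estimates can be
compared against it. What the generator does *not* emulate: realistic base
composition or k-mer structure, linkage disequilibrium between variants,
indels, overlapping or clustered miRNA families, expression levels, and
real pre-miRNAs' higher fraction of imperfect stem positions. The last
point matters for interpretation: synthetic hairpins are nearly perfect, so
few SNPs can *repair* a mismatch and the stabilizing ΔΔG class is rarer
than in real data, while the destabilizing class is commoner. Passing tests
therefore demonstrate correctness of the machinery and recovery of planted
signals, not that real-data class proportions will match.

# Problem sizes and numerical choices

The test suite uses studies of 8–500 loci on genomes of 0.05–1.2 Mb; the
folding oracle-equivalence suite uses 200 random sequences of 5–15 nt
(where exhaustive enumeration is cheap); permutation calibration uses 500
replicates of 200 permutations. These sizes give stable statistics (e.g.
planted region rates are recovered within 3 standard errors at 500 loci)
while keeping a full run in tens of seconds. All folding arithmetic is
integer centi-kcal, all simulations are seeded, and every pipeline run is a
pure function of (inputs, config, seeds) — two runs with the same
configuration produce byte-identical output trees.

# Known limitations

* The energy model is qualitative: no dangles, coaxial stacking, special
  tetraloops, or temperature dependence; absolute MFE values are not
  comparable with Turner-parameter implementations, only self-consistent
  differences are used.
* Target scanning is ungapped; bulged target sites are out of scope.
* Indels and structural variants are not handled anywhere in the pipeline.
* The conservation flag is exact-match (optionally small-Hamming) against a
  reference mature set; it does not model family-level or seed-only
  conservation.
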