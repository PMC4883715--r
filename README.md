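# mirvar

Genome-wide analysis of SNPs in plant microRNA precursors: where variants
fall, how they reshape hairpin stability, and how they rewire target
spectra.

## The problem

Single nucleotide polymorphisms inside a pre-miRNA hairpin can change the
folding free energy of the precursor (and hence its processing into mature
miRNA), and a SNP inside the mature miRNA itself can create or destroy
near-perfect complementarity with plant mRNA target sites. Population
resequencing projects deliver millions of SNPs; `mirvar` provides the
analysis layer on top: it assigns each variant to a region of a precursor
locus (mature miRNA, rest of the precursor, flanks, fixed windows, or
distance bins), compares per-region SNP densities, polarizes the
substitution spectrum by ancestral allele, folds wild-type and SNP-type
precursors to classify ΔΔG effects, enumerates SNP-type mature miRNAs and
their gained/lost targets under a two-predictor consensus, and runs a
permutation test for candidate miRNA sets with suspiciously low diversity
(e.g. domestication-related loci).

It is aimed at researchers doing regulatory/population genomics in plants
who have a genome FASTA, precursor annotations (GFF3/BED12), and a VCF —
or who want a fully synthetic, truth-tracked study to validate such a
pipeline.

## Methods in brief

* **Region assignment.** Coordinates are 0-based half-open internally;
  offsets are strand-aware, 5'→3' in transcript orientation. A variant in a
  mature sub-interval is labelled `mature` (precedence over the rest of the
  precursor); matched flanks have per-locus length equal to the precursor.
* **Density.** d = SNPs per base, averaged per locus; group summaries are
  mean ± s.e.; groups compared by one-way ANOVA with compact-letter
  pairwise display (Welch + Holm).
* **Spectrum.** Direction = ancestral → derived where the ancestral allele
  matches ref or an alt; transitions are A↔G and C↔T; Ts/Tv is the count
  ratio including unpolarized sites.
* **Folding.** Simplified nearest-neighbor energy model (six pair types,
  stacking matrix, loop penalties, affine multiloops) under a Zuker-style
  DP in C++, integer centi-kcal arithmetic, deterministic tie-breaks, with
  an exhaustive-enumeration oracle for short sequences.
  ΔΔG = MFE(SNP-type) − MFE(wild-type); ≥ 0.3 destabilizing, ≤ −0.3
  stabilizing, |ΔΔG| ≤ 0.05 unchanged, otherwise slight.
* **Targets.** Ungapped windows scored by two rule sets — A: weighted
  penalty (mismatch 1, G:U 0.5, doubled at positions 2–13, threshold 4);
  B: ≤ 1 seed defect (positions 2–8), no mismatch at 10–11, penalty ≤ 5 —
  and only consensus sites count. Gained = targets of the SNP-type miRNA
  not targeted by the wild type; lost = the converse.
* **Permutation test.** Mean candidate density vs `n_perm` random draws of
  the same size from the other loci; one-sided (lower) empirical
  p = (1 + #{null ≤ observed}) / (n_perm + 1).
* **Synthetic studies.** `sim_config()`/`simulate_study()` generate a toy
  genome with embedded hairpin loci (arm + loop + reverse-complement arm),
  variants at controlled per-region rates with a planted Ts:Tv odds,
  population tags, ancestral alleles, and transcripts with planted
  near-complementary target sites — with the ground truth kept alongside.

See `vignettes/mirvar-methods.Rmd` for the full account of models,
conventions, parameter defaults and limitations.

## Worked example

```r
library(mirvar)

cfg   <- sim_config(seed = 1, n_loci = 20, chrom_len = 100000)
study <- simulate_study(cfg)
study
#> <mirna_study> 2 chromosome(s), 20 loci, 447 variants, 30 transcripts

asn <- assign_regions(study, region_scheme("matched_flank"))
tab <- density_by_region(asn, study$loci, study$matures)
tab
#> <density_table> scheme: matched_flank
#>       group  n        mean          se
#>   precursor 20 0.017851334 0.002393853
#>      mature 20 0.016461039 0.005150818
#>    up_flank 20 0.007774699 0.002185879
#>  down_flank 20 0.005291149 0.001411720

density_anova(tab)
#> <anova_result> F = 3.9934 , p = 0.010709
#> letters: down_flank:a mature:ab precursor:b up_flank:a

substitution_spectrum(study$variants)
#> <spectrum_summary> 447 polarized + 0 unpolarized; Ts/Tv = 2.605 ( transition fraction 0.7226 )

ddg_table(study$loci[1:3, ], study$variants)[, c("locus_id", "pos", "ref",
                                                 "alt", "context", "ddg",
                                                 "effect_class")]
#>      locus_id  pos ref alt context ddg  effect_class
#> 1 syn-mir-001 2224   C   T    loop 0.0     unchanged
#> 2 syn-mir-002 2216   T   C    stem 3.5 destabilizing
#> 3 syn-mir-003 4367   C   A    stem 7.2 destabilizing
#> 4 syn-mir-003 4375   G   C    stem 2.4 destabilizing
```

Reading the output: the planted study enriches precursors for SNPs
relative to their matched flanks, and the density table recovers that
contrast (0.018/bp vs ~0.005–0.008/bp, ANOVA p ≈ 0.01 at only 20 loci;
letter `b` marks the precursor group as separated from both flanks). The
spectrum recovers the planted transition excess (Ts/Tv ≈ 2.6 against a
planted odds of 2.46 at n = 447). In the ΔΔG table, the loop SNP leaves the
fold untouched while the stem SNPs destabilize the hairpins by 2–7
kcal/mol under the internal energy model.

The same stages run end to end, with all tables written to disk, via:

```r
report <- run_pipeline(study, run_config(k = 3, n_perm = 500),
                       candidates = study$loci$id[1:3],
                       out_dir = "results/run1")
```

A thin command-line wrapper is included at `inst/scripts/mirvar.R`
(`simulate`, `run`, `fold` subcommands).

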