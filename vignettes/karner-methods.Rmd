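---
title: "Methods: conservation population genomics of the Karner blue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation population genomics of the Karner blue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karnerpop)
```

# Scope and model of the data

`karnerpop` re-implements, as a reusable and fully tested library, the
computational stages of a range-wide population-genomic analysis of the
endangered Karner blue butterfly (*Plebejus samuelis*) and four close
relatives (*P. melissa*, *P. fridayi*, *P. idas*, *P. anna*): read-alignment
cleanup for degraded museum specimens, depth-based genomic masking, locus
selection and export for external structure/migration tools, Reich's
small-sample F~ST~ with a Mantel isolation-by-distance test, cross-species
windowed diversity comparison with matched-pair testing, between-group
protein divergence, and a screen for fixed single-amino-acid variants
(SAVs) interpreted against residue burial. Genome assembly, read mapping,
SNP calling and the external inference binaries (STRUCTURE, BA3-SNPs,
smartpca, OmegaFold/DSSP) are deliberately out of scope: the package starts
from alignments, genotype calls, protein alignments and RSA tables, and
produces the inputs those tools consume and the statistics computed around
them.

All coordinates are 0-based half-open internally; 1-based conventions
appear only at the VCF boundary. Every threshold is surfaced in
`pipeline_config()` rather than hard-coded, because the thresholds *are*
the analysis.

# Read cleanup for degraded, contaminated specimens

Museum specimens contribute reads that may be contaminated or heavily
damaged. Two complementary protocols operate on ungapped alignments against
the reference.

**Protocol A** (`protocol_a()`) tiles each contig with 30-bp windows and
clusters the reads spanning each window: reads are ranked by identity to
the reference window (ties broken by read id, for determinism), the first
read founds a cluster, and each later read joins the first cluster whose
*founding* read is within one mismatch, else founds its own. A cluster is
*good* if its size is at least half the largest cluster's and its mean
mismatch count is within 2 of the best cluster's. With at most two good
clusters, members of the remaining clusters are discarded; with more than
two, the window is considered unresolvable and all its reads are
discarded. A read flagged in any window it spans is removed globally.

Two points were genuinely open and are resolved as package decisions:

* *Window step.* Whether the 30-bp "sliding" windows overlap is ambiguous;
  the default is non-overlapping tiling (`step = window_size`), which gives
  each read region a single verdict, with `step` configurable for
  overlapping evaluation.
* *Ambiguous bases.* `N` positions are mismatch-neutral: they neither match
  nor mismatch, so damaged bases cannot manufacture spurious clusters.

Reads spanning no complete window cannot be evaluated and are retained
(they are listed in the `not_evaluated` attribute rather than silently
passed).

**Protocol B** (`protocol_b()`) corroborates each read against everything
overlapping it: an overlapping read is *consistent* (overlap ≥ 20 bp,
identity > 95%), *inconsistent* (≥ 2 mismatches and identity < 95%), or
neither — the two published clauses are applied literally and are not
exhaustive, so the neutral bucket exists by design. A read survives iff
consistent reads outnumber twice the inconsistent ones. Under the strict
reading, an isolated read (0 > 0) fails; because the protocol's purpose is
corroboration we keep that strict default, with `keep_singletons = TRUE`
as the escape hatch for sparse data.

# Depth mask ("good positions")

`window_depth()` computes mean per-base depth in 100-bp windows (the final
partial window is normalized by its true width — the source procedure is
silent on this edge). `good_segments()` passes windows whose depth lies
within 0.25–2.5× the median (inclusive bounds) and emits maximal runs of at
least three consecutive passing windows (≥ 300 bp). Two further decisions:

* Depth is cohort-summed by default, producing one shared mask, matching a
  single genome-wide good-position count; per-sample masks can be built by
  calling the function per sample.
* The median is computed over windows with positive depth. Zero-inflation
  from unassembled regions would otherwise depress the median and
  dishonestly rescue low-coverage windows; zero-depth windows still fail
  the lower bound.

Because the thresholds are median-relative, the mask is invariant under
uniform scaling of depth — a property the test suite checks directly.

# Locus selection and export

Sample completeness is `present / (present + missing)` with the 30%
inclusion bar. Read literally, a present-to-*missing* ratio of 0.30 would
admit samples with 23% of positions called — an implausible bar — so the
completeness-fraction reading is the default and the literal odds reading
sits behind `mode = "odds"`.

`select_loci()` implements the two bi-allelic profiles (coverage at depth
> 2 in strictly more than 75% of samples for PCA, 50% for STRUCTURE; both
alleles in more than four samples — the allele rule is applied identically
in both profiles). `select_ba3_loci()` enforces at least two called samples
per locality, at least two alleles, and > 50 kb spacing via a left-to-right
greedy scan per contig (deterministic and maximal under the coordinate
ordering; loci on different contigs always satisfy spacing since
cross-contig linkage is unknown). Exports to STRUCTURE, BA3-SNPs and
EIGENSTRAT formats round-trip exactly through the package's own readers;
EIGENSTRAT stores dosages, so heterozygotes come back in canonical allele
order (`canonical_calls()`).

# Differentiation, geography and inbreeding

`reich_fst()` implements the sample-size-corrected moment estimator
designed for very small per-locality sample sizes (3–10 individuals per
locality is typical here). For allele counts $a_1, a_2$ out of $n_1, n_2$
chromosomes,

$$N = \left(\frac{a_1}{n_1}-\frac{a_2}{n_2}\right)^2
      - \frac{h_1}{n_1} - \frac{h_2}{n_2},\qquad
  D = N + h_1 + h_2,\qquad
  h_i = \frac{a_i (n_i - a_i)}{n_i (n_i - 1)},$$

combined across loci as a ratio of sums $\hat F = \sum N / \sum D$.
Localities with fewer than four individuals are excluded; negative
estimates are retained un-clipped to preserve unbiasedness (the
linearization $F/(1-F)$ handles them fine). The estimator is verified two
ways: exact agreement with an independently transcribed per-locus
brute-force implementation, and recovery of the island-model closed form
$F = 1/(1+4Nm)$ on simulated cohorts.

Great-circle distances use the haversine formula at the IUGG mean Earth
radius 6371.0088 km. `mantel_test()` correlates the upper triangles of the
distance matrix and the linearized F~ST~ matrix, with a one-sided
(positive-association) permutation null: rows and columns of one matrix are
permuted simultaneously and $p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + B)$.
The permutation count is not stated by the source analysis; the default is
9999 with an explicit seed. The identity permutation is excluded from the
draw, so perfectly correlated matrices attain the minimal p exactly.

Genotype PCA centers dosages and scales by $\sqrt{p(1-p)}$
(smartpca-style); it is plumbing for cluster visualization, not an
inference engine. `summarize_inbreeding()` reports the 2-decimal range of
per-locality inbreeding coefficients and flags values strictly above 0.1,
the conventional bar for concerning inbreeding.

# Cross-species diversity comparison

Rare alleles only surface in large samples, so each species is equalized to
random 13-sample subsets — drawn *fresh for each 10-kb window* under a
single seed (the source procedure draws per gene while reporting per
window; per-window is the default here and the choice is exposed via
`unit`). Positions called in fewer than two subset samples leave the
denominator; a position is multiallelic iff it carries ≥ 2 alleles each
seen in ≥ 2 subset samples (sample-counted, not chromosome-counted).

Because Karner blues were collected in 2010–2012 but comparison specimens
span 1899–2021, raw comparisons would inflate apparent diversity in the
older material. `match_pairs()` therefore pairs each comparison-species
sample pair (year gap $y$, distance $d$) with a Karner pair with year gap
≥ $y$ and distance in $[d, 2d]$; among eligible candidates the closest
distance wins, ties broken lexicographically, and candidates may be reused
(reuse is not prohibited by the procedure; the Karner candidate pool is
much larger than the comparison pool, keeping reuse rare).
`paired_one_sided_test()` then applies the paired t-test with the
"comparison species greater" alternative.

`loss_of_diversity_windows()` flags windows with a significantly *low*
multiallelic count in the focal species and significantly *high* counts in
both comparison species, by exact binomial tails at α = 0.01. The null
proportion is each species' own genome-wide mean ratio — the only null
available internally. Raw p-values are reported to mirror the published
procedure; Benjamini–Hochberg columns are available behind `adjust`.
`genes_in_regions()` pads genes by 2000 bp for regulatory context
(truncated at contig ends) and reports genes whose padded span overlaps
flagged windows by ≥ 70%.

# Protein divergence and the SAV screen

Between-group protein divergence considers *good positions* (called in
strictly more than 40% of samples of both groups) of proteins with more
than 200 good positions; a position is divergent iff both groups have a
> 70% consensus residue (a tie for most-frequent disqualifies — "most
frequent" is undefined under ties) and the consensus residues differ.
Proteins above the mean divergence in all three pairwise group comparisons
feed `enrich_terms()`, a generic one-sided binomial enrichment against the
good-position background (term databases are user input, not shipped).

`find_sav_candidates()` screens for fixed, potentially deleterious
variants using four criteria, evaluated over called samples only (coverage
is already gated by criterion 1): (1) the position is called in > 50% of
focal samples and, per comparison species, in more than
max(5, 20% of samples); (2) ≥ 95% of called focal samples share one
residue — read inclusively, since exactly 95% is attainable at real sample
sizes and excluding it would be arbitrary; (3) every comparison species has
its own ≥ 80% dominant residue, different from the focal one; (4) the focal
residue occurs in ≤ 5% of each comparison species. "More than 5" is
implemented strictly (≥ 6), relaxable via `other_min_samples`.
`classify_burial()` consumes a DSSP-normalized relative solvent
accessibility table and calls a residue exposed iff RSA is strictly above
25%; missing RSA leaves candidates retained but unclassified.

# What the synthetic generators emulate — and what they do not

The generators exist so every downstream stage is testable with planted
truth and no downloads. They reproduce the *statistical structure* each
stage assumes, not sequencing physics:

* `simulate_cohort_genotypes()` draws ancestral frequencies uniformly on
  [0.05, 0.95] and deme frequencies from a Beta distribution whose
  intraclass correlation equals the island-model expectation
  $1/(1+4Nm)$ — chosen precisely because it makes the closed form an
  exact oracle for the F~ST~ estimator. Inbreeding is per-individual
  identity-by-descent: with probability *f* one allele draw is duplicated,
  so the heterozygosity deficit $1 - H_o/H_e$ targets *f* directly. A
  stepping-stone mode places demes on an east–west line with per-step
  drift, generating genuine isolation by distance for the Mantel
  machinery. Default sizes mirror the study's sampling reality (a handful
  of individuals per locality, thousands of loci).
* `simulate_read_stack()` plants exactly `round(divergence × length)`
  substitutions per contaminant read rather than Binomial-sampling them: at
  a 10% divergence over 30 bp, Binomial sampling would leave ~18% of
  contaminants within one mismatch of the reference — indistinguishable
  from natives *by the protocol's own definition* — making planted-truth
  recovery an ill-posed target. The deterministic count keeps every plant
  detectable while preserving the stated per-base rate. Truth labels live
  in a sidecar table the cleanup code never sees.
* `simulate_protein_panel()` plants SAVs as focal-fixed/other-fixed
  residue splits (satisfying all four criteria by construction) and
  divergent positions as 80/20 residue mixtures in the two groups — above
  the 70% consensus rule yet far from the 95% prevalence bar, so the two
  kinds of plants can never be confused. Non-planted positions carry a
  single shared residue plus optional exchangeable noise.
* `simulate_depth_track()` keeps ordinary windows inside 0.8–1.2× the
  target median and plants dropouts/spikes at 0.05×/5×, guaranteeing they
  sit outside the 0.25–2.5× band.

None of the generators model sequencing-error profiles, indels, selection,
or linkage disequilibrium. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under the assumed structure, not
robustness to artifacts real libraries contain.

# Numerical choices and problem sizes

Determinism is end-to-end: every stochastic function takes a seed, and the
demonstration pipeline (`run_pipeline()`) writes a manifest with MD5 hashes
that reproduce byte-identically under a fixed configuration. Ties are
always broken by explicit ordering (read ids, sample ids, coordinates).
Degenerate inputs fail loudly: constant matrices in the Mantel test,
zero-variance differences in the paired t, F = 1 in the linearization,
all-zero depth tracks.

The simulation-based checks run at deliberately desk-scale sizes chosen to
make their Monte-Carlo error small relative to the tolerance being
asserted: 5000 loci for the null F~ST~ bias check (|bias| < 0.01), 20
replicates of 2000 loci for island-model recovery, 500 replicate Mantel
tests for null-uniformity (Kolmogorov–Smirnov at α = 0.01), 200 null and
50 effect replicates for the matched-pair test's size and power. The
published real-data figures (Mantel r = 0.73 across 22 localities, 6863
BA3 loci, genome-wide median ratios, the 30-SAV/6-buried counts) depend on
the deposited sequencing data and external tools and are treated as
reference context, not as desk-reproducible targets; the one printed input
the package does ship is the 22-locality inbreeding-coefficient table
(`inst/extdata/locality_inbreeding.tsv`), whose summary (range 0.17–0.45,
all localities above the 0.1 bar) the acceptance script recomputes.

# Known limitations

* Cleanup protocols assume ungapped alignments; indel-containing reads are
  out of scope (as is mapping itself).
* The island-model oracle is exact only in expectation; at few loci the
  ratio-of-sums estimator has visible Monte-Carlo spread, which is why
  replicate-level confidence intervals, not point equality, are asserted.
* The matched-pair construction reuses candidates; with small candidate
  pools this induces dependence between pairs that the t-test ignores. The
  type-I calibration check runs at realistic pool ratios where the effect
  is negligible.
* `enrich_terms()` is mechanics only — it has no ontology topology,
  term propagation, or annotation database.
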