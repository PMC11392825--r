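# karnerpop

Conservation population genomics of the Karner blue butterfly (*Plebejus
samuelis*), an endangered North American species sampled at 3–10
individuals from each of 22 localities across Wisconsin, Michigan, Indiana
and New York, and compared against four close relatives (*P. melissa*,
*P. fridayi*, *P. idas*, *P. anna*) whose museum specimens are often
degraded and contaminated. `karnerpop` packages the bespoke computational
stages of that kind of analysis as a tested, reusable R library, for
conservation geneticists working with many loci but very few individuals
per population:

* **Read cleanup** for degraded alignments: window-cluster filtering
  (Protocol A) and overlap-corroboration filtering (Protocol B).
* **Depth masking**: "good position" segments from 100-bp windowed depth
  within 0.25–2.5× the median, in runs of ≥ 3 windows.
* **Locus selection & export**: completeness and coverage filters, the
  more-than-four-samples allele rule, 50-kb spacing for migration-model
  input, and round-trip-safe STRUCTURE / BA3-SNPs / EIGENSTRAT / VCF
  writers.
* **Differentiation & isolation by distance**: Reich's small-sample F_ST
  estimator, combined across loci as a ratio of sums

      N = (a1/n1 - a2/n2)^2 - h1/n1 - h2/n2,   D = N + h1 + h2,
      h_i = a_i (n_i - a_i) / (n_i (n_i - 1)),   F_ST = sum(N) / sum(D)

  plus haversine distances and a seeded one-sided Mantel permutation test
  of F_ST/(1 − F_ST) against geographic distance.
* **Cross-species diversity**: windowed multiallelic ratios on equalized
  13-sample subsets, year/distance matched-pair construction with a
  one-sided paired t-test, loss-of-diversity windows by exact binomial
  tails, and padded-gene overlap reporting.
* **Protein screens**: between-group protein divergence, binomial term
  enrichment, and a four-criteria screen for fixed single-amino-acid
  variants (SAVs) with relative-solvent-accessibility burial calls.
* **Synthetic data**: seeded generators for multi-deme cohorts (island or
  stepping-stone), contaminated read stacks, depth tracks and protein
  panels with planted truth, so the whole pipeline runs and is testable
  with no external data.

## Worked example

Simulate a stepping-stone cohort (six localities on an east–west line,
five diploids each, migration between neighbours), estimate pairwise
differentiation and test for isolation by distance:

```r
library(karnerpop)

model <- demographic_model(n_demes = 6, deme_size = 1000,
                           migration_rate = 0.005, n_loci = 800,
                           n_samples_per_deme = 5, inbreeding_f = 0.3,
                           structure = "stepping_stone", seed = 11)
cohort <- simulate_cohort_genotypes(model)
cohort$genotypes
#> genotype_matrix: 30 samples x 800 loci, 6 localities
#>   missing calls: 5.0%

fst <- reich_fst(cohort$genotypes, min_samples = 4)
fst
#> fst_matrix: 6 localities (Reich estimator)
#>        L01    L02    L03    L04    L05    L06
#> L01 0.0000 0.0587 0.0768 0.0860 0.1009 0.1300
#> L02 0.0587 0.0000 0.0709 0.0764 0.0948 0.1283
#> L03 0.0768 0.0709 0.0000 0.0610 0.0904 0.1155
#> L04 0.0860 0.0764 0.0610 0.0000 0.0523 0.0820
#> L05 0.1009 0.0948 0.0904 0.0523 0.0000 0.0586
#> L06 0.1300 0.1283 0.1155 0.0820 0.0586 0.0000

d <- haversine_matrix(cohort$meta)[fst$localities, fst$localities]
mantel_test(d, standardize_fst(fst), n_permutations = 999, seed = 11)
#> Mantel test: r = 0.928, one-sided p = 0.001 (999 permutations)
```

Differentiation grows along the line (F_ST 0.059 between neighbours, 0.130
across the full span) and the Mantel test detects the isolation-by-distance
signal the generator planted. The per-locality heterozygosity deficit
recovers the simulated inbreeding coefficient of 0.3:

```r
round(wright_f(cohort$genotypes), 3)
#>   L01   L02   L03   L04   L05   L06
#> 0.243 0.291 0.267 0.243 0.259 0.300
```

Summarizing the published 22-locality inbreeding table shipped with the
package flags every locality as high-inbreeding (coefficient strictly
above 0.1), with coefficients ranging 0.17–0.45:

```r
tbl <- read_inbreeding_table(system.file("extdata",
    "locality_inbreeding.tsv", package = "karnerpop"))
str(summarize_inbreeding(tbl), digits.d = 3)
#> List of 4
#>  $ min         : num 0.17
#>  $ max         : num 0.45
#>  $ n_localities: int 22
#>  $ flagged     : chr [1:22] "2" "3" "5" "6" ...
```

A one-command synthetic demonstration of every stage, with a reproducible
manifest:

```r
run_pipeline(pipeline_config(seed = 7), "runs/demo")
```

## Documentation

The methods vignette (`vignettes/karner-methods.Rmd`) documents the
models, the thresholds and their defaults, the deliberately resolved
ambiguities (window stepping, ambiguous-base handling, strict-vs-inclusive
boundaries), what the synthetic generators do and do not emulate, and known
limitations.
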