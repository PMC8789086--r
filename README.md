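# popgenpipe

An integrated R toolkit for the population-genetic analysis of diploid
biallelic SNP panels from structured populations — the statistical pipeline
behind studies of the demographic history of indigenous South American
groups: who shares recent ancestry with whom, how strong and how old the
founder events were, and how effective population size changed through the
European contact period.

For population geneticists and statistical-genetics developers, the package
provides, behind one consistent data model:

* **Panel IO and QC** — VCF 4.x (via `vcfR`), PLINK-style and
  EIGENSTRAT-style text; missingness / Hardy–Weinberg (exact mid-p) /
  chromosome-arm filters; sliding-window LD pruning
  (r² > 0.2 in 50 kb / 10 kb windows).
* **A forward Wright–Fisher simulator** (`simulate_panel`) with
  Balding–Nichols founder differentiation, Poisson recombination,
  bottlenecks, admixture pulses, splits with founder events and migration —
  plus `plant_fixtures` for exact planted IBD/ROH/pedigree truth. Every
  downstream method is verified against this ground truth.
* **f-statistics** with weighted block-jackknife errors:
  f2/f3/f4, outgroup-f3 distance matrices (1 − f3), F4 affinity counts
  (Z > 4), and admixture-graph fitting that minimizes the worst residual
  |Z|, with one-way/two-way placement search.
* **Structure and geography** — supervised ancestry by EM (the ≥ 99%
  focal-ancestry filter), allele-frequency-normalized PCA, classical MDS,
  great-circle distances, and isolation-by-distance regression with a
  Mantel-style permutation test.
* **Relatedness and inbreeding** — PLINK-style PI_HAT
  (= P(IBD=2) + P(IBD=1)/2), exact maximum-unrelated-set selection
  (threshold 0.375), PLINK-style ROH calling and F_ROH.
* **IBD segments** — likelihood seed-and-extend detection on phased
  haplotypes (> 2 cM, support > 3), 0.6 cM gap merging, window-likelihood
  local ancestry and ancestry masking, segment dating
  (E[generations] ≈ 3/2I, 28 y/generation), period stratification
  (≤ 8.4 cM pre-Columbian, ≤ 28 cM colonial, > 28 cM recent), and
  sample-size-normalized sharing networks.
* **Demography** — founder age/intensity from the exponential decay of
  allele-sharing correlation (`A·exp(−2·FA·d) + c`), and N_e history from
  the IBD length spectrum via the closed form
  `(2g(G−u)+1)·e^(−2gu)` weighted by coalescence probabilities.
* **Hierarchical AMOVA** with level-appropriate permutation tests
  (populations among groups, individuals among populations, haplotypes
  among individuals).
* **`run_pipeline()`** to orchestrate all stages from one seeded
  configuration.

## Worked example

Simulate two demes with a founder event, recover it, and date an IBD
segment:

```r
library(popgenpipe)

model <- demographic_model(
  c(F = 800, O = 300),
  chromosomes = data.frame(chrom = as.character(1:10),
                           length_cm = 40, n_snps = 400),
  n_generations = 11, fst = 0.05,
  events = list(list(type = "bottleneck", deme = "F",
                     start_gen = 1, duration = 1, size = 20)))
sim <- simulate_panel(model, c(F = 25, O = 15), seed = 8002)

panel <- sim$panel
outgroup <- panel$sample_ids[panel$sample_table$population == "O"]
curve <- allele_sharing_decay(panel, "F", outgroup, max_cm = 20,
                              bin_cm = 0.25)
fit_founder_event(curve, bootstrap_n = 100, seed = 8002)
#> founder_event: FA = 10.8 generations (301 y), FI = 0.39%

segment_age(8.4)
#>   generations years
#> 1    17.85714   500
bin_to_period(c(5, 12, 40))
#> [1] "precolumbian" "colonial"     "recent"
```

The founder fit recovers the planted event: the bottleneck happened 10
generations before sampling and the fitted age is 10.8 generations
(~300 years at 28 years/generation), with the 95% chromosome-bootstrap CI
[8.7, 12.8] covering the truth. `segment_age` shows the length–time calibration used
to stratify IBD sharing into historical periods: an 8.4 cM segment dates
to ~17.9 generations ≈ 500 years ago, the European contact horizon.

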