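# ciscogen

Genomic resilience analysis for small, isolated cold-water fish populations.

Cisco (*Coregonus artedi*) and similar lacustrine salmonids persist near the
southern edge of their range as tiny, completely isolated lake populations.
Whether such a population survives lake warming depends on an interplay of
genetic drift, mutational load, immune-gene diversity and the physical
availability of cold, oxygenated water. `ciscogen` implements the full
analysis chain a population-genomics study of such a system needs, with a
seeded synthetic-data generator for every input so the whole pipeline is
testable without field data:

* **Genotype filtering** — call-rate / missingness / minor-allele-frequency
  filters in the conventional order, an HDPlot-style paralog screen
  (heterozygote fraction `H`, pooled read-ratio deviation
  `D = (ref - n/2) / sqrt(n/4)`, allele balance), and one-SNP-per-RAD-tag
  thinning.
* **Population genetics** — observed/expected heterozygosity and the
  inbreeding coefficient `G_IS = 1 - Ho/He`; multi-locus Weir–Cockerham
  θ (ratio of summed variance components) with Slatkin linearization
  θ/(1−θ); Nei's `D_A`; neighbour-joining trees with locus-bootstrap
  support; four-level hierarchical AMOVA (within individuals / among
  individuals in lakes / among lakes in lineages / among lineages) with
  permutation tests; Mantel and partial Mantel tests; the inverse-size *di*
  distance; and LD-based effective population size (Burrows composite r²,
  Waples bias correction `1/S + 3.19/S²`, cross-linkage-group locus pairs).
* **Mutational load** — classification of nonsynonymous variants as
  putatively deleterious by effect score (≤ −2.5), and the two load metrics
  `AF_del` (mean deleterious-allele frequency) and `Prop_del` (fraction of
  catalog loci segregating per population).
* **MHC diversity** — presence/absence haplotype calling from multi-copy
  amplicon read counts (dataset-wide >50 reads, within-individual >10% of
  reads, singleton removal), resampling rarefaction of haplotype richness,
  and a Nei–Gojobori codon Z-test for historical balancing selection
  (dN > dS).
* **Oxythermal habitat** — TDO3 (temperature at the DO = 3 mg/L depth),
  7/30-day moving-window maxima, cumulative oxythermal stress dosage
  (degree-days of TDO3 above 17 °C), and oxythermal habitat
  thickness/volume, from daily temperature and dissolved-oxygen profiles.
* **Correlation stage** — VIF/pairwise-r collinearity pruning, redundancy
  analysis with permutation ANOVA, multiple regression with exact lmg
  relative-importance decomposition, and univariate regressions.

Everything is tidyverse-shaped: results come back as tibbles or carry
`tidy()`/`glance()` methods, and the main result types have
`autoplot()`/`plot_*()` displays.

## Worked example

Simulate a two-lineage study system (defaults emulate long-isolated inland
lakes: between-lineage F ≈ 0.135, within-lineage F ≈ 0.255), filter it, and
measure structure:

```r
library(ciscogen)

ds <- simulate_genotypes(sim_config(n_loci = 1000,
                                    n_individuals_per_pop = 20, seed = 42))
ds
#> <genotype_dataset> 120 individuals x 1000 loci; 6 populations, 2 lineages

filtered <- filter_genotypes(ds)$dataset |>
  hdplot_screen() |> _$dataset |>
  select_snp_per_tag()

diversity_stats(filtered)
#> # A tibble: 6 × 6
#>   population     n    Ho    He      G_IS prop_poly
#> 1 L1P1          20 0.247 0.248  0.00134      0.767
#> 2 L1P2          20 0.256 0.258  0.00825      0.778
#> ...

round(unclass(pairwise_fst(filtered)), 3)
#>       L1P1  L1P2  L1P3  L2P1  L2P2  L2P3
#> L1P1 0.000 0.254 0.280 0.354 0.355 0.368
#> L1P2 0.254 0.000 0.240 0.319 0.343 0.344
#> ...

glance(amova(filtered, permutations = 199, seed = 1))
#> # A tibble: 1 × 5
#>        F_IS  F_SC  F_CT  F_IT permutations
#> 1 -0.000707 0.255 0.117 0.341          199
```

Within-lineage pairs differentiate at θ ≈ 0.24–0.28 and cross-lineage pairs
at θ ≈ 0.32–0.37, and the AMOVA attributes the variance accordingly
(F_SC ≈ 0.26 among lakes within lineages, F_CT ≈ 0.12 among lineages) — the
drift-dominated structure such systems show in practice.

The package also ships a compiled survey of 29 inland cisco lakes
(`cisco_sites()`, `cisco_population_metrics()`) used as the worked input for
the correlation stage:

```r
mt <- build_metrics_table()
fit <- rda_genetics(
  mt[, c("Ho", "prop_poly_rapture", "G_IS", "af_del", "prop_del",
         "n_hap", "prop_poly_mhc")],
  mt[, c("latitude", "surface_area_km2", "max_depth_m", "tdo3_max")],
  permutations = 999, seed = 1)
fit
#> <rda_result> constrained fraction 0.457, adjusted R2 0.366, global p 0.001
#>          predictor  variance         F p_value
#> 1         latitude 1.6060861 10.138207   0.001
#> 2 surface_area_km2 0.8508983  5.371184   0.010
#> 3      max_depth_m 0.3337783  2.106932   0.053
#> 4         tdo3_max 0.1451515  0.916250   0.527
```

Latitude and lake surface area drive the genetic metrics; depth is marginal
and the oxythermal ceiling (TDO3) explains essentially nothing — isolation
and lake size, not modelled oxythermal stress, structure the genetics.

`run_pipeline(pipeline_config(seed = 1))` chains all stages end-to-end on
synthetic data and returns every intermediate table plus a manifest of
seeds, thresholds and content hashes for bit-identical reruns.

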