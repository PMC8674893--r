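---
title: "Methods: models, estimators and design choices in ciscogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in ciscogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ciscogen` analyses the genomic resilience of small, isolated cold-water
fish populations: how drift, mutational load, immune-gene diversity and
oxythermal habitat relate across a set of lake populations. This vignette
documents the statistical models, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the places where the
design was genuinely open and a choice had to be made.

## The synthetic study system

Every analysis stage can be exercised on generated data with known truth.

**Genotypes.** `simulate_genotypes()` draws allele frequencies down a
two-level hierarchy under the Balding–Nichols model: an ancestral frequency
$p_0 \sim \mathrm{Uniform}(m, 1-m)$ (default floor $m = 0.05$), a lineage
frequency $\mathrm{Beta}\!\left(p_0\frac{1-F_L}{F_L},
(1-p_0)\frac{1-F_L}{F_L}\right)$, and population frequencies drawn the same
way around the lineage value with $F_P$. $F = 0$ degenerates to copying the
parent frequency, and $F \ge 1$ is rejected. Genotypes are binomial draws;
read depths are Poisson with mean `mean_depth / 2` per allele copy (default
20 reads per genotype). Defaults $F_L = 0.135$ and $F_P = 0.255$ mirror the
hierarchical structure typical of long-isolated inland-lake systems (AMOVA
$F_{CT}$ near 0.14, $F_{SC}$ near 0.26, compounding to mean pairwise
$F_{ST}$ near 0.36). Balding–Nichols was chosen deliberately over a
coalescent simulator: the estimators under test only care about marginal
allele-frequency differentiation, so no ancestry or recombination machinery
is warranted. Consequences: the generator produces *no* linkage
disequilibrium (loci are independent), no site-frequency-spectrum realism,
and no IBD geography — tests that pass here say the estimators are correct,
not that the generator is a faithful model of cisco demography.

**MHC reads.** `simulate_mhc_reads()` gives each individual $k$ true
haplotypes ($k$ uniform on `copies_range`, default 1–4, as expected when
primers amplify several duplicated MHC genes), allocates reads by a
Dirichlet-multinomial (concentration 20) *conditioned on every true
haplotype strictly exceeding `min_call_frac` of the individual's reads*
(default 0.10, the nominal calling threshold) — the generator guarantees by
construction that its truth is recoverable by a threshold caller, rather
than merely making failures rare. One caveat remains by design: a true
haplotype carried by exactly one individual in the dataset is removed by
the caller's singleton rule, so recovery comparisons are made against the
truth restricted to multi-carrier haplotypes. The generator also diverts a
Binomial(`total_reads`, `noise_rate`)
share of reads (default 2%) to a small pool of shared noise haplotypes,
mimicking PCR/sequencing artefacts that recur across individuals but stay
far below the within-individual calling threshold.

**Lakes.** `simulate_lake_profiles()` builds a logistic thermocline between
a 4 °C hypolimnion and a sinusoidal seasonal epilimnion peak, and depletes
dissolved oxygen below the thermocline linearly in time at
`hypolimnetic_do_decay` mg L⁻¹ day⁻¹. Both profiles are monotone
non-increasing in depth, so threshold crossings are unique and available in
closed form; the generator returns them in a truth block, and the metric
code must reproduce them by interpolation within 0.05 °C / 0.05 m. This is
a geometric stand-in for hydrodynamic model output: it has the right shape
for exercising crossing/interpolation logic but no weather, mixing events,
or multi-modal profiles.

**Coding alleles.** `simulate_cds_alleles()` writes random stop-free coding
sequences, injects single-nucleotide substitutions whose
synonymous/nonsynonymous status is controlled exactly, attaches a uniform
effect score on `score_spread` to each nonsynonymous allele, and emits the
alignment-report table an external protein aligner would produce. Scores
are exact, so classification recall and precision are 1 by construction —
the tests verify plumbing, not the scorer.

## Filtering

`filter_genotypes()` applies, in a fixed order: locus call rate (< 70%
removed), individual missingness (> 50% removed), minor allele frequency
(< 0.01 removed; a MAF exactly at the threshold is retained), then an
optional requirement that every population retain at least one genotyped
individual per locus. MAF is recomputed after the individual removal —
removing individuals changes allele counts, and the stage report records
the order so either convention can be audited. "Genotyped in every lake" is
interpreted as at least one genotyped individual per population, the
weakest defensible reading.

The paralog screen (`hdplot_screen()`) pools reads across heterozygotes per
locus: allele balance $= \mathrm{ref}/n$, read-ratio deviation
$D = (\mathrm{ref} - n/2)/\sqrt{n/4}$ (a pooled-binomial z-score with
$\sigma = \sqrt{n \cdot 0.25}$), and $H$ the heterozygote fraction. Flags
are strict comparisons against $H > 0.5$, $|D| > 15$, and balance outside
(0.3, 0.7). A locus with no heterozygotes has undefined $D$ and balance and
cannot be flagged by those criteria. `select_snp_per_tag()` keeps the
highest-MAF SNP per RAD tag, breaking ties by the lexicographically lowest
locus id so the choice is reproducible.

## Population-genetic estimators

**Diversity.** Per locus, $H_e = \frac{2n}{2n-1}(1 - \sum p^2)$ (Nei's
unbiased gene diversity); $H_o$ is the heterozygote fraction; both averaged
over loci, and $G_{IS} = 1 - \bar H_o / \bar H_e$. A monomorphic population
has $H_e = 0$ and an undefined $G_{IS}$, reported as `NA`.

**Differentiation.** Multi-locus Weir–Cockerham θ is the ratio of
locus-summed variance components $\sum a / \sum (a+b+c)$; raw (possibly
negative) pairwise values are reported, and negatives are floored at zero
only inside the Slatkin linearization θ/(1−θ). "Standardized $F_{ST}$" is
ambiguous across programs, so plain θ is the default with a
heterozygosity-based Hedrick standardization behind a flag; the IBD
machinery consumes θ. Nei's
$D_A = 1 - \frac{1}{L}\sum_l \sum_{\text{alleles}} \sqrt{p_X p_Y}$ feeds
neighbour joining (via `ape`); bootstrap support resamples loci with
replacement and counts bipartitions.

**AMOVA.** Four nested levels on allele indicators, with Excoffier-style
sums of squares. Components are solved per locus with that locus's
unequal-sample-size coefficients (missing genotypes change the coefficients
locus by locus) and summed. Permutation nulls are tailored per statistic:
gene copies among individuals within populations for $F_{IS}$, individuals
among populations within lineages for $F_{SC}$, whole populations among
lineages for $F_{CT}$. Note the granularity limit: with $G$ lineages of $P$
populations the $F_{CT}$ null has only $\binom{GP}{P}$ distinct states, so
small designs cannot reach small p-values no matter how many permutations
run — the function warns when a lineage holds a single population.

**Mantel.** Pearson correlation of the upper triangles, one-tailed p by
jointly permuting rows/columns of the first matrix; the partial version
uses the standard first-order partial correlation, recomputed under the
same permutations. A constant matrix is an error, not a silent `NA`.

**LDNE.** Burrows' composite disequilibrium per locus pair over
pair-complete observations,
$\hat\Delta = \frac{S}{S-1}\left(\frac{\overline{XY}}{2} - 2\hat p\hat
q\right)$, $\hat r^2 = \hat\Delta^2 / (\hat p(1-\hat p)\hat q(1-\hat q))$,
restricted to pairs on different linkage groups and to loci with allele
frequencies at or above `p_crit` (default 0.05) within the population. The
sample-size-weighted mean $r^2$ is reduced by the random-mating sampling
expectation $1/S + 3.19/S^2$ (the $S \ge 30$ form; study-scale samples
qualify) and inverted via
$N_e = (1/3 + \sqrt{1/9 - 2.76\,r^2{}'})/(2 r^2{}')$. A non-positive
residual or negative discriminant yields `Inf` — the standard signal that
the sample resolves no drift LD, not evidence of a huge population.
Parametric/jackknife confidence intervals are out of scope. Two caveats the
user inherits from the method: pooling samples from distinct gene pools
biases the estimate downward (Wahlund), and the sampling theory assumes the
sample is a small fraction of the cohort — the package's own validation
breeds a cohort of $4N$ offspring before sampling for exactly this reason.
The bias correction is calibrated for the Burrows form specifically; a
plain squared Pearson correlation of dosages has a smaller small-sample
expectation and would inflate $N_e$ by tens of percent at $S = 40$.

**The *di* distance.** The literature phrase "distance based on the
inverse" of a size proxy admits two readings; both are implemented —
`sum_inverse` ($1/v_i + 1/v_j$, the drift expectation, default) and
`abs_diff_inverse` ($|1/v_i - 1/v_j|$) — and neither is claimed as the
canonical published form. The function rejects non-positive values rather
than silently taking `log` of sub-km² areas.

**Geography.** Equirectangular projection about the mean latitude, in km —
adequate at regional scale (checked against great-circle distances to
within 2%).

## Mutational load

`annotate_coding()` consumes an external aligner's tabular report (the
aligner and the effect scorer are interfaces, not re-implementations:
database-dependent steps are not desk-reproducible), keeping hits with
overlap strictly above 40 aa and identity strictly above 90%, best identity
per locus. Alleles are translated in the aligned frame/strand; a stop
gained before the final codon excludes the locus. `classify_deleterious()`
designates the allele scoring ≤ −2.5 as deleterious. On the conventional
effect-score scale a neutral alternative allele has score above the
threshold, i.e. > −2.5 (a "≥ 2.5" reading would be off-scale); when both
alleles score ≤ −2.5 the lower-scoring allele wins and the entry is flagged
`both_deleterious` rather than dropped. `load_metrics()` computes `af_del`
(unweighted mean deleterious-allele frequency over catalog loci; loci with
no genotyped individuals in a population drop out of that population's mean
but never out of the `prop_del` denominator) and `prop_del` (fraction of
the full catalog segregating in the population). A minor-allele-based
designation is available as a mode for comparison with studies that assume
purging keeps deleterious variants rare.

## MHC haplotypes

Thresholds apply in the order printed on the tin: dataset-wide read total
strictly above 50, then within-individual presence strictly above 10% of
that individual's raw read total, then removal of haplotypes present in
exactly one individual. "Found once in the dataset" is interpreted as one
*individual* (the error-removal rationale concerns artefacts private to one
sample), not one read. Copy number is never inferred; the matrix is
strictly binary. Rarefied richness resamples `rarefaction_n = 5`
individuals without replacement 1000 times (both configurable, seeded); a
population at or below the rarefaction size is computed at its own size and
flagged, where the resampling mean equals the exact distinct count.
Per-haplotype carrier frequencies are renormalized to sum to one because
multi-copy carriage makes raw carrier frequencies sum above one.

The Nei–Gojobori test counts fractional synonymous sites per codon and
pathway-averaged differences per codon pair, excluding mutational pathways
that pass through a stop codon (falling back to all pathways if every
ordering is blocked) and counting changes *to* stops as nonsynonymous in
site counting. $d_N$ and $d_S$ are pairwise proportions averaged over all
pairs; variances come from bootstrapping codon columns, and
$Z = (d_N - d_S)/\sqrt{\widehat{\mathrm{Var}}(d_N) +
\widehat{\mathrm{Var}}(d_S)}$ with a one-tailed p for $d_N > d_S$ —
elevated $d_N$ at MHC is the classic signature of historical balancing
selection. Codons containing ambiguous bases are skipped and counted.

## Oxythermal metrics

Threshold crossings scan downward from the surface and linearly interpolate
the first bracketing grid pair; a grid value exactly at the threshold
returns that depth. Conventions for degenerate days: a column entirely
below 17 °C pins the thermal crossing to the surface (0 m); a column
oxygenated to the bottom leaves TDO3 undefined and extends habitat
thickness to the bottom; DO below 3 mg/L at the surface pins the DO
crossing to 0 m. Thickness $z_{DO=3} - z_{T=17}$ is deliberately signed:
negative thickness means the oxygen boundary sits above the 17 °C
isotherm — no simultaneously cold and oxygenated layer exists. Yearly
metrics: maximum daily TDO3; maxima of 7- and 30-day centered moving
averages computed over defined days only, with a window undefined below 50%
defined days; COSD as $\sum_{\text{days}} \max(0,\ \mathrm{TDO3} - 17)$
°C·day with undefined days contributing zero (a degree-day reading of
cumulative stress dosage, with both thresholds as conventionally printed);
minimum thickness, and minimum volume as thickness × surface area
(km²·m). Lake-years with fewer than 30 defined TDO3 days are flagged. The
long-term summary reports, per metric, the mean over years and the
bottleneck extreme — maximum for the heat metrics, minimum for
thickness/volume: always the worst year for a cold-water fish. The season
window defaults to all simulated days and accepts an explicit day range,
since open-water periods vary by lake and year.

## Correlation stage

Collinearity pruning removes the largest-VIF predictor iteratively until
all VIF < 5 (at most $p-1$ iterations), then inspects pairwise $|r| > 0.7$:
which member of a merely-correlated pair to keep is a scientific judgement,
so the caller must name it in `manual_drops` — an unresolved pair is an
error listing the offenders, never a silent choice.

RDA centers and unit-scales both blocks (responses on heterogeneous scales
would otherwise weight arbitrarily), fits via `vegan::rda`, and reports the
constrained variance fraction, Ezekiel-adjusted R², a global permutation
test and per-predictor tests — marginal (leave-one-out) by default because
no fitting order is privileged when predictors are reported individually;
sequential tests are available behind `by = "terms"`. The regression stack
runs on raw scales so R² values are comparable with published univariate
fits; surface area is log-transformed where named. The lmg decomposition is
computed by exact subset enumeration ($2^p$ regressions, practical to
$p \approx 12$); raw shares sum to the model R² and normalized shares to 1,
identities the tests enforce at $10^{-9}$. $N_e$ is carried through the
metrics table but excluded from response matrices by default: infinite
estimates and strong sample-size sensitivity make it unusable as a
response.

The package ships a transcribed 29-lake survey table
(`cisco_population_metrics()`, `cisco_sites()`) as a realistic worked input
for this stage; the acceptance script recomputes its aggregate statistics
and the RDA/lmg results at run time.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains the stages with plain tabular handoffs and a
manifest of seeds, thresholds and content hashes; identical configs produce
bit-identical manifests. Every stochastic routine takes an explicit integer
seed and restores the caller's RNG state, so results never depend on
ambient RNG history. There is no shell entry point: the package is an
analysis library, and the exported functions plus this vignette are its
interface; `write_genotypes_vcf()` emits plain-text VCF for handoff to
external tools (the reader uses `vcfR`).

Test and validation problem sizes were chosen as the smallest that make the
statistical checks sharp: 2000 loci for Balding–Nichols θ recovery (±0.03),
20 replicates of a Wright–Fisher cohort ($N_e = 100$, 500 unlinked loci, 40
sampled of 400 offspring) for LDNE (median within a factor of 1.5),
200–300 null simulations for Mantel/RDA test size (0.05 ± 0.02 and p-value
uniformity), full $\binom{10}{5}$ enumeration for the rarefaction oracle,
and 0.25 m depth grids for the oxythermal closed-form checks.

## Known limitations

The generators validate estimators, not biology: no linkage, no coalescent
ancestry, no hydrodynamics, no read-level sequencing error model. The
AMOVA permutation granularity bounds attainable p-values in small designs.
LDNE confidence intervals are not provided. The Nei–Gojobori stop-codon
conventions follow one defensible reading among several; the oracle in the
test-suite enumerates the same definition, so the tests pin the
implementation to its documented convention rather than to any external
program's output.
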