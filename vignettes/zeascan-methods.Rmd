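---
title: "Methods: models, parameters and design choices in zeascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in zeascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`zeascan` implements a complete population-genomic analysis of maize
domestication (teosinte vs. maize) and adaptation (tropical vs. temperate
maize): haplotype-window sharing, two selective-sweep scan statistics with
empirical sweep calling, permutation-based co-localization with GWAS
signals, and a mixed-model association stage. This vignette is the
package's account of the underlying models, the tunable parameters and
their defaults, the numerical choices, and what the built-in simulator can
and cannot tell you about real data.

## The synthetic cohort generator

Real SNP-array cohorts of this design (hundreds of maize inbred lines,
~190 teosinte accessions, ~40k filtered SNPs) are not redistributable with
a package, so every stage here is exercised against `simulate_cohort()`.
The generator is a first-class, tested component, not a fixture.

**Population tree.** The topology is fixed to the inferred *Zea* lineage:
*parviglumis* and *mexicana* descend from a common teosinte ancestor;
maize descends from the *parviglumis* branch (a single domestication); the
temperate pool derives from the tropical one. Concretely, ancestral
frequencies are drawn per SNP and drifted along edges with the
Balding–Nichols kernel

> p_child ~ Beta( p (1−F)/F, (1−p)(1−F)/F ),

which has mean p and variance F·p(1−p). Tropical maize drifts from the
*realized* parviglumis frequencies (the maize-ancestor bottleneck is folded
into the tropical edge), and temperate drifts from tropical. Edge F values
are per-population parameters (`population_spec()`), defaulting to 0.08
(*parviglumis*), 0.12 (*mexicana*), 0.18 (tropical), 0.12 (temperate).
These were chosen once so that (i) pairwise Weir–Cockerham F_ST lands in
the 0.10–0.21 band reported for the four real subgroups, with the
tropical–temperate contrast smallest, and (ii) expected heterozygosity
declines parviglumis > mexicana > tropical > temperate, the diversity
ordering the haplotype bootstrap is expected to reproduce.

**Ancestral frequencies** are Beta(0.8, 0.8) truncated to [0.05, 0.95]
(inverse-CDF sampling). The U-shape mimics ascertained array SNPs; the
truncation keeps SNPs polymorphic after drift so window statistics do not
collapse to degenerate cases.

**Mating models.** Teosinte accessions are outbred: two haplotypes drawn
independently per SNP (Hardy–Weinberg). Maize lines are fully inbred: one
haplotype drawn and duplicated, so heterozygosity is exactly zero before
missingness masking. Inbred allele frequencies still estimate the
population frequency without bias, but carry n rather than 2n independent
draws — relevant wherever denominators matter (documented in
`allele_freq()`).

**Sample sizes** default to 75 *parviglumis* / 96 *mexicana* (the real
teosinte subgroup sizes) and 150 tropical / 100 temperate maize —
desk-scale stand-ins for the real 669/157 chosen to keep the full test
suite in minutes while leaving every group ≥ 75 samples so the
equal-size haplotype bootstrap applies unchanged.

**Linkage.** SNPs are independent draws; LD arises only through population
structure and planted sweeps. This is the generator's main departure from
real data (below).

**Planted sweeps.** `plant_sweep()` applies a star-like hitchhiking
transform: a SNP at distance d from the sweep center escapes with
probability c = 1 − exp(−r·d/s̃) (r = recombination rate per bp, default
1e-8, i.e. 1 cM/Mb; s̃ = unitless sweep strength). The target population's
frequency moves to c·p + (1−c)·B, where B ∈ {0,1} is one per-sweep draw of
the hitchhiking background allele (B = 1 with probability equal to the
pre-sweep frequency at the center SNP), and haplotypes are re-drawn from
the new frequencies. This transform deliberately matches the alternative
model inside the composite-likelihood scan, so parameter recovery by
`xpclr_scan()` is a well-posed test — a coupling to keep in mind: it
validates the implementation, not the model's fit to real sweeps.

**Phenotypes.** `simulate_phenotype()` builds
y = Σ effectₖ·dosageₖ + g + e with g ~ N(0, σ_g² K) on the realized
kinship K and σ_g² scaled so h² = σ_g²/(σ_g² + noise_sd²). This emulates a
BLUP-like flowering-time trait with known causal SNPs; it contains no
GxE, dominance or epistasis.

## Genotype statistics

Filters follow the array-QC conventions: SNPs with ≥ 20% missing calls are
removed (strict `<` retained), monomorphic SNPs dropped, MAF thresholds
inclusive (`>= min_maf`). PIC uses the PowerMarker definition for
biallelic markers, PIC = 1 − p² − q² − 2p²q²; the source tooling does not
print its formula, so this standard definition is adopted and the
frequencies are plain observed frequencies.

Coordinates are 1-based VCF positions externally; all windows are
half-open [start, end) in bp internally, with SNP position p occupying bp
index p − 1. Boundary conventions (a signal on the first bp of a sweep
co-locates; one just past the end does not) follow from this choice and
are pinned by tests.

## Structure diagnostics

PCA operates on the standardized relationship matrix: dosages mean-imputed
per SNP, centered by 2p, scaled by sqrt(2p(1−p)), K = ZZ'/m. Mean
imputation biases individual placements slightly toward the centroid but
keeps K positive semi-definite; IBS distances instead use pairwise-complete
SNPs, matching common tooling. Neighbor joining is Saitou–Nei via `ape`;
negative branch lengths are clamped to zero (counted and reported), and
outgroup rooting resolves the root on the outgroup's pendant edge. The
Q-matrix assignment rule is the study's: membership ≥ 0.70 assigns the
sample to that cluster, otherwise "Mix"; the boundary is inclusive and
ties (possible only with low thresholds and > 2 clusters) break to the
lowest cluster index, deterministically.

## Window haplotypes

The genome is tiled into non-overlapping 50-kb windows; windows with more
than five SNPs get a seeded random subset of exactly five (the same subset
for every individual), so each locus carries one to five SNPs. Each phased
haplotype over the subset is an allele; haplotypes containing a missing
allele are excluded from counts rather than imputed, because no
phasing-quality model is available at array density.

Rarefaction richness is the standard expectation
Σᵢ [1 − C(N−Nᵢ, g)/C(N, g)] for a subsample of g haplotypes; it is
monotone in g and never exceeds the observed allele count. (Published
summaries of this analysis type can print "richness" above the mean
per-locus count, which standard rarefaction cannot produce; the package
implements the standard quantity and does not attempt to reproduce such
values.)

Group-specific haplotypes are evaluated against the explicitly supplied
comparison set, not every group in the catalog. The shared-ancestry
partition assigns every maize-observed haplotype to exactly one of MPM
(present in both teosintes), MM (mexicana only), PM (parviglumis only) or
M (maize-private); percentages are over maize-observed distinct haplotypes
and sum to 100 by construction.

`bootstrap_equalize()` subsamples 75 samples per group, 100 times, without
replacement by default — "bootstrap" in the source description reads as
repeated subsampling since the smallest group is used whole; a
with-replacement switch is provided. Both haplotypes of an inbred line
enter the counts (the pooling convention is configurable upstream by
filtering samples).

## Selection scans

**Weir–Cockerham F_ST.** Per SNP, the two-population variance components
a (between populations), b (between individuals within populations) and c
(within individuals) are computed from sample sizes, allele frequencies
and observed heterozygosities; θ = a/(a+b+c) may legitimately be negative.
Windows (100 kb sliding, 10 kb step, ≥ 5 SNPs) score the *weighted* ratio
Σa / Σ(a+b+c) — a ratio of sums, not a mean of per-SNP ratios, which the
tests distinguish on a crafted example. Negative window scores are kept
as-is so the empirical quantile thresholds are unbiased.

**Composite likelihood (XP-CLR-style).** The original tool is configured
in the source analysis only through its settings (100-kb/10-kb windows,
exactly five SNPs per window); the likelihood internals here are therefore
a documented simplification of the Chen–Patterson–Reich model: observed
test-population frequencies are treated as plug-in data (no binomial
sampling layer); under the null they are Normal(p_ref, ω·p_ref(1−p_ref))
truncated to [0,1] with boundary mass absorbed at the edges; under a sweep
at the window center each SNP escapes with probability
cᵢ = 1 − exp(−r·dᵢ/s̃) and the density is the two-component mixture
p_ref·N(cᵢp_ref + (1−cᵢ), ωv) + (1−p_ref)·N(cᵢp_ref, ωv). The drift scale
ω is estimated genome-wide by the method of moments
(mean (p_test−p_ref)²/(p_ref(1−p_ref)) over SNPs with p_ref ∈ (0.05,0.95)),
which recovers the Balding–Nichols F in expectation. The CLR maximizes the
weighted alternative log-likelihood over s̃ ∈ {0.001, 0.005, 0.01, 0.05,
0.1} and is floored at zero; SNP clusters with reference-population
r² > 0.95 are down-weighted by 1/cluster-size, the package's rendering of
LD-based SNP weighting. The reference population defaults to teosinte
(domestication) and tropical maize (adaptation); both are configurable.

## Sweep calling and combination

The two-step empirical rule is implemented as: compute P90 and P99.5 over
*window* scores; mark windows ≥ P90; merge overlapping/adjacent marked
windows into candidate regions; retain regions whose maximum member window
reaches P99.5. The source description is ambiguous about whether the 0.5%
cut applies to windows or merged regions; this reading (both quantiles on
the window distribution, outlier test on the region maximum) follows its
order of operations and is fixed by tests. With all scores identical there
are no strict outliers and the call returns an empty set with a warning.
Quantiles use R's default type-7 interpolation, under which n distinct,
non-adjacent windows yield exactly round(0.005·n) retained regions.

Sweeps closer than 100 kb merge (strict `<`; a gap of exactly 100 kb does
not merge). Two methods' sweeps are "common" when they overlap by ≥ 1 bp
(configurable); the joint set is the union with overlapping regions
merged, so set sizes follow the inclusion–exclusion arithmetic
(e.g. 295 + 141 − 42 = 394).

## Co-localization and the permutation null

A sweep co-locates with a point signal when the signal lies within
[start − flank, end + flank), and with an interval signal (known genes as
BED) on ≥ 1 bp overlap. The enrichment test re-places the same number of
regions with the same lengths uniformly at random (chromosome chosen
proportional to length among chromosomes the region fits; start uniform;
overlaps among placed regions permitted — a rejection-sampling switch is
not needed at the sparsities involved) and counts co-located regions
(or, by switch, hit signals). The empirical p-value uses the add-one
correction p = (1 + #{perm ≥ obs})/(n_perm + 1), so p ∈ [1/(n_perm+1), 1]
and p = 0 is impossible. With 1000 permutations the strongest attainable
evidence is p ≈ 0.001, the bound the enrichment claim is tested against.

One calibration subtlety: with few short regions the permutation statistic
is a small, lumpy count and the achievable p-values skip across any fixed
α, so uniformity checks need configurations with enough granularity
(dozens of regions with non-trivial hit probability). The package's null
calibration test uses 60 regions of 500 kb against 100 signals on a
5 × 20 Mb genome for this reason.

## Mixed-model association

`mlm_scan()` follows the EMMA/P3D scheme: eigendecompose the kinship once,
estimate the variance ratio λ = σ_g²/σ_e² by REML on the null model
(1-D optimization of the profiled restricted likelihood over log λ in
[−12, 12]), then test every SNP by GLS with λ fixed. Covariates default to
the intercept plus the first three kinship principal components; the Wald
t statistic is referenced to n − q − 1 degrees of freedom, which makes the
scan *exactly* OLS when K = I — the equivalence the oracle test asserts to
1e-6. Missing dosages are mean-imputed per SNP; MAF < 0.05 SNPs are
excluded by default; non-PSD kinship inputs are repaired by eigenvalue
clamping with a message. Per-environment scans and BLUP construction are
out of scope: the scan accepts any phenotype vector, so a BLUP column can
be supplied directly.

Significant SNPs resolve to loci by merging consecutive significant SNPs
within 1 Mb — the merge distance is an explicit assumption (the source
analysis does not state its rule) and is configurable. The Bonferroni
cutoff is 1/m with m the LD-pruned SNP count (PLINK-style pruning: 50-SNP
blocks, step 50, remove the later SNP of any pair with r² ≥ 0.2).

## Problem sizes used by the test suite

The suite runs the full pipeline at desk scale, chosen as the package's
own testing conditions: sweep recovery uses 10 replicates of a 10 × 20 Mb
genome with 20k SNPs, 50 + 50 contrasted samples and five planted sweeps
(s̃ = 0.05, 300-kb half-width); estimator checks use 5,000 SNPs at
n = 50/50; the haplotype bootstrap uses ~1,000 loci over a 10 × 5 Mb
genome with the default sample sizes; permutation calibration uses 200
replicates. All stochastic checks fix their seeds.

## Known limitations

* No within-population LD: the simulator cannot exercise haplotype-block
  structure, so the LD down-weighting path is tested on constructed
  correlated SNPs rather than realistic decay.
* The sweep transform equals the scan's alternative model; detection power
  on real sweeps (soft sweeps, standing variation, recombination-map
  heterogeneity) is outside what passing tests demonstrate.
* Statistical phasing is assumed done upstream; unphased cohorts are
  refused by the haplotype stage rather than phased internally.
* Multiallelic sites, indels and structural variants are skipped at VCF
  ingestion; imputation is limited to per-SNP means inside PCA/kinship/GLS.
* The membership-probability inputs to `assign_groups()` come from
  external structure software (or simulation truth); the clustering
  algorithm itself is deliberately not reimplemented.
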