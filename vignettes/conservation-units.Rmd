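---
title: "Methods: delineating conservation units from SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineating conservation units from SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `frogcu`, the
assumptions behind each stage, the defaults and why they were chosen, and
the limits of what the simulation-based tests demonstrate. The package is
organised around the workflow used to evaluate conservation units (CUs) in
desert amphibian populations: filter a RADseq SNP panel, split it into
candidate-adaptive and neutral marker sets, quantify diversity,
differentiation and effective size from the neutral set, model functional
connectivity with a gravity model, and compare candidate management-unit
groupings with AMOVA.

## The genotype substrate

All genetic computations run on a `geno_matrix`: an individuals × SNPs
integer matrix of alternate-allele counts (0/1/2, `NA` for missing) with
per-SNP metadata (locus, position within locus, mean depth), per-individual
site assignments and a site registry with projected metre coordinates.
Genotypes are unphased; nothing in the package uses phase or strand.
VCF input is parsed with `vcfR`; multi-allelic records are excluded and
counted, since every downstream statistic assumes biallelic markers.

## Filter cascade

`apply_filter_cascade()` applies nine steps in a fixed order (individuals
with > 55% missingness; markers absent from any site; global minor allele
count < 10; mean depth outside [6, 100]; call rate < 80%; loci carrying
more than 7 SNPs; one SNP per locus; Hardy–Weinberg deviation; paralogue
screen). Decisions a user may care about:

* "MAC > 9" is interpreted strictly: markers with MAC ≥ 10 are kept.
* The depth filter uses the *mean* depth across genotyped individuals.
  Per-genotype depth thresholds are a plausible alternative; the mean was
  chosen because the container stores one depth summary per SNP and the
  filter's purpose (flagging collapsed repeats and dropouts) concerns the
  marker, not the call.
* One SNP per locus keeps the highest-MAC SNP; ties break to the smallest
  position within the locus, making the cascade deterministic.
* The HWE screen uses a two-sided exact test on heterozygote counts
  conditional on allele counts (no mid-p), evaluated only at sites with at
  least 10 individuals; a SNP is removed when p < 0.05 at five or more
  such sites. Testing within sites avoids mistaking Wahlund structure for
  genotyping error.
* The paralogue screen removes SNPs heterozygous in *every* genotyped
  individual at any site with at least 7 genotyped individuals — the
  signature of collapsed duplicated loci.

The cascade is idempotent on its own output and its report reconciles
(removed + remaining = input) at every step; both are property-tested.

## Diversity and differentiation

Expected heterozygosity uses the small-sample unbiased form
$\hat H_E = \frac{2n}{2n-1}\,2\hat p(1-\hat p)$ with $n$ the genotyped
diploids. Nucleotide diversity is the sum of per-SNP unbiased
heterozygosities divided by an explicit assayed length: with
reduced-representation data π depends on how many monomorphic bases were
assayed, so the denominator is a parameter (`assayed_length`, defaulting to
90 bp × number of markers to mimic 90 bp RAD loci) rather than a hidden
convention.

Weir–Cockerham θ is computed from the per-locus variance components
a (among populations), b (among individuals within populations) and
c (within individuals), aggregated as a ratio of sums across loci — the
standard multi-locus recommendation, less biased than averaging per-locus
ratios. Negative estimates are retained; truncation at zero would bias
means of many near-zero pairs. Loci monomorphic within a pair carry no
information about that pair and are skipped. Pairwise θ on tiny instances
is tested against an independent scalar coding of the 1984 component
formulas, and on Balding–Nichols simulations against the generator's F.

Nei's standard distance averages the homozygosity sums $J_x$, $J_y$,
$J_{xy}$ over loci before forming $I$ and $D=-\ln I$; identical frequency
vectors give D = 0 and fully fixed opposite alleles give D = ∞ (stored as
`Inf`, never truncated). Gene flow for the gravity stage is `1 − D`.

## LD effective population size

`estimate_ne_ld()` implements the linkage-disequilibrium method for a
single site sample:

1. Markers are screened to within-site call rate ≥ 80% and minor allele
   frequency ≥ Pcrit (defaults 0.05 and 0.10; a marker below Pcrit is
   dropped entirely). Screening out rare alleles controls the strong
   upward bias they induce in r².
2. For every locus pair, the squared Burrows composite correlation of
   genotype codes is computed with Weir's small-sample factor:
   $\hat r^2 = \left(\frac{S}{S-1}\right)^2
   \frac{\widehat{\mathrm{cov}}(g,h)^2}{\widehat{\mathrm{var}}(g)\,\widehat{\mathrm{var}}(h)}$,
   where S is the number of individuals genotyped at both loci. This
   composite form needs no phase or random-mating assumption; under
   Hardy–Weinberg genotype frequencies it coincides with the scaled
   Pearson correlation of genotype codes, which is the cross-check used in
   the tests. Numerically, the package verified at build time that this
   convention reproduces the sample-size expectation below to within 0.2%
   at S = 16, 30 and 50 on LD-free data.
3. The drift signal is $\hat r^2' = \overline{\hat r^2} - E(r^2_S)$ with
   $E(r^2_S) = 1/S + 3.19/S^2$ for S ≥ 30 (else
   $0.0018 + 0.907/S + 4.44/S^2$), S taken as the harmonic mean of
   per-pair sample sizes; the inversion
   $\hat N_e = (1/3 + \sqrt{1/9 - 2.76\,\hat r^2'})/(2 \hat r^2')$
   (small-sample variant below S = 30) maps it to an effective size.
   Non-positive $\hat r^2'$ or a negative discriminant means no resolvable
   drift signal and yields `Inf`.
4. Confidence intervals use a delete-one-*individual* jackknife on
   $\hat r^2'$, mapped through the same monotone inversion (so the lower
   r² bound gives the upper Ne bound). The individual jackknife was chosen
   over a locus-pair jackknife because locus pairs sharing a locus are not
   independent, which makes pair-resampling intervals anti-conservative.
5. Point estimates and intervals are also reported after division by
   $0.098 + 0.219 \ln C$ with C = 13 chromosome pairs, the correction for
   unremovable physical linkage appropriate to ranid karyotypes; the
   divisor is < 1 for realistic C, so corrected estimates are larger.

For tractability the pairwise computation caps the marker set
(`max_loci`, default 2000, deterministic even thinning); locus pairs carry
diminishing information well before that point.

## Genotype–environment association

Candidate adaptive markers are detected at the *site* level: the response
is the sites × SNPs allele-frequency matrix, the predictors are site-level
environmental variables (screened for pairwise |r| < 0.6), and population
structure can be removed by conditioning on leading principal components
(partial RDA; the pipeline default is 7 conditioning PCs, configurable —
there is no objective rule, and the synthetic island model needs none, so
the simulation-based power checks run unconditioned). Ordination is
delegated to `vegan::rda()`; an independent centre/residualise/SVD
evaluation backs it in the tests. SNP columns are centred but not
variance-scaled, the common choice for frequency responses.

Outliers are flagged per constrained axis at |z| ≥ 3.5 after
standardising the loadings (mean and SD over all SNPs on that axis), then
unioned across the first two axes; z-scoring makes the rule invariant to
vegan's axis scaling and sign conventions. Each candidate is assigned the
predictor with the largest |Pearson r| to its response column. With
loadings approximately normal under neutrality the expected flagged
fraction per axis is 2Φ(−3.5) ≈ 4.6 × 10⁻⁴, which the tests verify on a
pure-noise panel of 40,000 markers. Batch (sequencing-lane) effects reuse
the same machinery with the batch indicator as the lone predictor and a
stricter ±4 SD threshold.

## Gravity models

Functional connectivity is modelled as a singly constrained gravity model
on a site graph. Graphs are Delaunay triangulations (Bowyer–Watson,
implemented in the package and tested against the empty-circumcircle
definition) or saturated, optionally pruned by maximum edge length
(50 km for fitting; 15 km — a dispersal-capacity bound — for
prediction). Covariates on edges are medians of the raster cells under the
straight segment (buffered samples for widths above the native 30 m cell;
the tests confirm medians are stable across 30–510 m widths on smooth
surfaces); at-site covariates are the raster values at the origin node.
Node metrics (degree, Freeman–Brandes betweenness on the unweighted graph,
alpha centrality with α = 0.85/λ_max and unit exogenous input) come from
`igraph`, with betweenness verified against exhaustive path enumeration.

The model takes natural logs of the flow (`1 − Nei's D`) and of every
covariate and fits
`ln_flow ~ ln_dist + Σ ln_v + Σ ln_c + (1 | origin)` with `lme4`, the
random intercept on the edge's origin site absorbing the non-independence
of edges sharing a site. The origin is defined as the lower-indexed node
at graph construction — an arbitrary but recorded and reproducible choice.
Covariates that can be ≤ 0 (e.g. temperature in °C) are shifted by
`1 − min` before the log; shifts are stored on the fit and re-applied at
prediction, so train/predict transformations always agree.

Model competition uses ML fits and AICc with
k = fixed effects (incl. intercept) + 2 variance parameters; reported
coefficients and Wald 95% CIs come from REML refits. A hypothesis's
"number of landscape parameters" (distance + at-site + between-site terms)
is reported separately from k, since the two counts answer different
questions. Fits that emit convergence failures are flagged and excluded
from the ΔAICc baseline. Prediction is at population level (random effects
zero) with the Duan smearing estimator φ = mean(exp(residual)) correcting
the retransformation bias; predictions above 1 (impossible on the
`1 − D` scale) are clipped with a logged count, and flows ≥ 0.85 —
the working definition of a connected pair — are flagged.

## AMOVA

`run_amova()` decomposes variance among groups, among sites within groups
and within sites, operating on individual genotype vectors with squared
Euclidean distance (the common SNP treatment; no within-individual
stratum, matching the three-stratum reporting convention). Markers are
pruned to < 5% missingness and remaining gaps mean-imputed per SNP —
deterministic with bounded distortion. Variance components use the
standard nested unequal-sample-size coefficients; negative components are
reported and flagged rather than truncated, degenerate inputs (zero total
variance) are flagged, and percentages must sum to 100 ± 0.1 (tested).
The implementation works from sums of squares around means; the test
oracle recomputes everything from pairwise distances, an algebraically
equivalent but independent route. `compare_groupings()` ranks candidate
delineations by percent among-group variance, reporting group counts
alongside because a delineation of singleton sites can win the percentage
while being useless for management.

## The simulators and what the tests do (and do not) show

`simulate_genotypes()` draws neutral deme frequencies from the
Balding–Nichols beta model, whose expected F_ST equals the parameter F —
that closed form is the oracle for the differentiation tests (defaults:
31 sites × 12 diploids, 5000 neutral + 50 adaptive markers, F = 0.2,
5% missingness, Poisson depth with mean 29, mirroring a realistic RADseq
design for this system). An optional two-level hierarchy (groups at
`fst_between`, demes within groups) supports the AMOVA ranking tests.
Adaptive loci respond logistically to a standardised environmental
predictor with slope 2 per SD plus frequency noise (SD 0.03) — strong,
detectable selection by design, appropriate for testing detection
machinery rather than estimating realistic power. The landscape is a
30 km square at 30 m resolution (a compact stand-in for a regional study
area) with linear-trend-plus-smoothed-noise covariate surfaces.

`simulate_wf_sample()` runs a single isolated Wright–Fisher diploid
population (default 4N generations from Uniform(0.2, 0.8) frequencies,
free recombination) and genotypes a sample; its closed-form
heterozygosity decay $H_t = H_0(1 - 1/2N)^t$ and the LD-Ne CI coverage on
Ne = 50 / 2000 loci / 30 sampled are the Ne oracles.
`simulate_gravity_flows()` generates ln-flows from known coefficients with
site and residual Gaussian noise; 50-replicate refits check 95% CI
coverage, and a ~10⁴-edge fit checks the smearing factor against the
lognormal mean exp(σ²/2).

What passing these tests does *not* show: the generators have no
sequencing-error or allele-dropout model, no linkage, no isolation by
distance within groups, no age structure (LD-Ne in age-structured samples
is biased low), and environmental selection acts locus-by-locus with no
polygenic architecture. Real data violate all of these; the tests
establish correctness of the estimators under their own assumptions, not
robustness to violations.

## Numerical conventions

* All randomness flows from one seed through deterministic sub-seeds
  (`sub_seed(seed, label)`), so identical configurations are bit-identical.
* Duplicate coordinates are jittered by < 1 m with a warning before
  triangulation; fully collinear points fall back to a nearest-neighbour
  chain.
* Imputation ties resolve to the lower genotype code; one-SNP-per-locus
  MAC ties resolve to the smaller position; both are documented
  tie-breaks, not incidental behaviour.
* Infinite values are first-class: Nei's D and Ne estimates may be `Inf`
  and propagate through corrections and CI bounds unchanged.
* Test problem sizes (5000-locus panels, 25 Wright–Fisher replicates,
  50 gravity refits, 100-trial brute-force comparisons) were chosen as the
  smallest sizes at which the oracle tolerances are comfortably
  identifiable.

## Known limitations

Cross-region divergence summaries for the published Nevada dataset require
the supplementary pairwise F_ST matrix, which is not redistributed here;
the bundled reference tables cover the printed per-site summaries only.
Stream distances and other routed covariates are accepted as precomputed
pairwise tables (`attach_edge_table()`); hydrological routing, resistance
surfaces and circuit-theory connectivity are out of scope, as are
coalescent simulation, ancestry-based imputation and temporal-method Ne.
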