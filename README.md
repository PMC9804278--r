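# frogcu

Conservation-unit delineation from SNP genotypes for naturally fragmented
amphibian populations, modelled on the Great Basin Columbia spotted frog
(*Rana luteiventris*) system: small breeding sites scattered across a xeric
landscape, RADseq-scale biallelic SNP panels, strong drift, and management
questions about which sites belong together.

The package is aimed at conservation geneticists who need to go from a
filtered VCF (or a simulated panel with known truth) to the quantities that
drive evolutionarily-significant-unit and management-unit decisions:

* **SNP filter cascade** — per-individual missingness, common-marker,
  minor-allele-count, depth, call-rate, SNPs-per-locus, one-SNP-per-locus,
  Hardy–Weinberg and all-heterozygote (paralogue) screens, with a
  step-by-step report (`apply_filter_cascade()`).
* **Diversity and differentiation** — observed/expected heterozygosity and
  nucleotide diversity per site (`site_diversity()`); multi-locus
  Weir–Cockerham θ as the ratio of summed variance components
  `θ = Σa / Σ(a+b+c)` (`pairwise_fst_wc()`, `global_fst_wc()`); Nei's
  standard distance `D = −ln I`, `I = J_xy/√(J_x J_y)`
  (`nei_distance_matrix()`).
* **LD effective population size** — squared Burrows composite correlation
  r̂² across locus pairs, corrected by the sample-size expectation
  `E(r²_S) = 1/S + 3.19/S²` (S ≥ 30) and inverted to
  `N̂e = (1/3 + √(1/9 − 2.76 r̂²'))/(2 r̂²')`, with delete-one jackknife CIs
  and the chromosome-number correction
  `N̂e / (0.098 + 0.219 ln C)` (`estimate_ne_ld()`, `chromosome_correct()`).
* **Genotype–environment association** — (partial) redundancy analysis on
  site allele frequencies, with candidate adaptive SNPs flagged at ±3.5 SD
  of the constrained-axis loadings and assigned to their most-correlated
  predictor (`fit_rda()`, `detect_outliers_sd()`); RDA-based batch-effect
  removal at ±4 SD (`remove_batch_effect()`).
* **Gravity models of functional connectivity** — Delaunay or saturated
  site graphs (`build_graph()`), node metrics (degree, betweenness, alpha
  centrality), edge-median landscape covariates from rasters, and the singly
  constrained log-linear mixed model
  `ln T_ij = β₀ + β_w ln w_ij + Σ β_v ln v_i + Σ β_c ln c_ij + u_i + ε_ij`
  fitted by ML for AICc competition and REML for coefficients, with
  Duan-smearing back-transformed flow prediction (`fit_gravity()`,
  `rank_models_aicc()`, `predict_flow()`).
* **AMOVA comparison of groupings** — three-level variance decomposition
  (among groups / among sites / within sites) to rank candidate
  management-unit delineations (`run_amova()`, `compare_groupings()`).
* **Simulators with known truth** — Balding–Nichols island (optionally
  hierarchical) genotypes with environmentally selected loci
  (`simulate_genotypes()`), Wright–Fisher populations for Ne validation
  (`simulate_wf_sample()`), autocorrelated landscape rasters
  (`make_landscape()`) and gravity flows (`simulate_gravity_flows()`), all
  driven by one seed.

`run_pipeline()` chains the stages (filter → candidate scan → neutral set →
diversity/differentiation → Ne → gravity → AMOVA) and writes every table
plus a JSON manifest.

## Worked example

```r
library(frogcu)

cfg <- sim_config(seed = 42, n_sites = 12, n_ind_per_site = 12,
                  n_neutral = 1500, n_adaptive = 25, target_fst = 0.15,
                  landscape_extent = 15000)
sim <- simulate_genotypes(cfg)
sim$gm
#> <geno_matrix> 144 individuals x 1525 SNPs, 12 sites, 5.0% missing

filt <- apply_filter_cascade(sim$gm, filter_config(min_global_mac = 5))
head(site_diversity(filt$gm), 3)
#> # A tibble: 3 x 7
#>   site_id     n    ho    he      pi private_alleles assayed_length
#> 1 S01        12 0.332 0.333 0.00370               0         137160
#> 2 S02        12 0.333 0.331 0.00368               0         137160
#> 3 S03        12 0.329 0.331 0.00368               0         137160

mean(tidy(pairwise_fst_wc(filt$gm))$value)
#> 0.158        # the generator was asked for F_ST = 0.15

wf <- simulate_wf_sample(true_ne = 50, n_loci = 2000, n_sample = 30, seed = 1)
estimate_ne_ld(wf, "WF1", ne_config(pcrit_values = 0.05))
#>   pcrit n_loci ne_raw ne_corrected ne_lo ne_hi
#>    0.05    325   51.4         77.9  55.1 129.2
```

The raw LD estimate (51.4) brackets the true size of 50; the corrected
column shows the same estimate inflated by the 13-chromosome-pair divisor
0.6597, the adjustment used when physically linked loci cannot be excluded.
Per-site heterozygosities sit near the island-model expectation for the
requested differentiation, and the mean pairwise θ of 0.158 recovers the
target within sampling error.

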