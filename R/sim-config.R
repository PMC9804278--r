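#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' a network of breeding sites on a desert landscape, RADseq-style biallelic
#' SNP panels with island-model structure, a handful of environmentally
#' selected loci, missing genotypes and Poisson read depths, plus the true
#' gravity-model coefficients used to generate connectivity flows.
#'
#' Defaults mirror the sampling design of the Nevada spotted frog system:
#' 31 sites of 12 diploids, thousands of neutral SNPs, moderate
#' differentiation (`target_fst = 0.2`), ~5% missing calls and ~29x depth.
#' The landscape is a compact 30 km square at 30 m resolution so that whole
#' pipelines remain cheap to simulate.
#'
#' @param seed master seed; all generator randomness derives from it.
#' @param n_sites number of sites (at least 2).
#' @param n_ind_per_site diploid individuals per site.
#' @param n_neutral,n_adaptive numbers of neutral and environmentally
#'   selected loci.
#' @param target_fst Balding-Nichols differentiation parameter `F` in (0,1).
#' @param n_groups optional number of higher-level groups; when greater than
#'   1 a two-level hierarchy is simulated with `fst_between` among groups
#'   and `target_fst` among sites within groups.
#' @param fst_between among-group differentiation when `n_groups > 1`.
#' @param env_gradients named list of covariate gradient specs
#'   (`trend_x`, `trend_y`, `noise_sd`, `smooth`, `offset`), one raster each.
#' @param selection_strength slope (per SD of environment) of the logistic
#'   response of adaptive-locus allele frequency to the environment.
#' @param adaptive_noise_sd SD of the frequency noise added to adaptive loci.
#' @param missing_rate per-genotype missingness fraction in [0,1).
#' @param depth_mean mean of the Poisson per-genotype read depth.
#' @param landscape_extent side of the square landscape (m).
#' @param cell_size raster resolution (m).
#' @param gravity_truth named coefficients of the true gravity model
#'   (`intercept`, `dist`, plus at-site/between-site covariate names).
#' @param sigma_site,sigma_resid SDs of the site random effect and edge
#'   residual in simulated ln-flows.
#' @param wf_ne true effective size for Wright-Fisher runs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 31L,
                       n_ind_per_site = 12L,
                       n_neutral = 5000L,
                       n_adaptive = 50L,
                       target_fst = 0.2,
                       n_groups = 1L,
                       fst_between = 0.1,
                       env_gradients = default_env_gradients(),
                       selection_strength = 2,
                       adaptive_noise_sd = 0.03,
                       missing_rate = 0.05,
                       depth_mean = 29,
                       landscape_extent = 30000,
                       cell_size = 30,
                       gravity_truth = default_gravity_truth(),
                       sigma_site = 0.10,
                       sigma_resid = 0.20,
                       wf_ne = 50L) {
  assert_that(is_count(n_sites) && n_sites >= 2, "n_sites must be >= 2")
  assert_that(is_count(n_ind_per_site), "n_ind_per_site must be a count")
  assert_that(is_count(n_neutral), "n_neutral must be a count")
  assert_that(n_adaptive >= 0, "n_adaptive must be non-negative")
  assert_that(is_fraction(target_fst, 0, 1), "target_fst must be in (0,1)")
  assert_that(is_fraction(missing_rate, 0, 1, open_lo = FALSE),
              "missing_rate must be in [0,1)")
  assert_that(landscape_extent > 0 && cell_size > 0,
              "landscape extent and cell size must be positive")
  if (n_adaptive == 0 && selection_strength != 0) {
    stop("selection_strength set but n_adaptive = 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Default landscape covariate gradients
#'
#' Four covariates shaped like the drivers used in frog connectivity work:
#' compound topographic index (cti), heat load index (hli), warmest-month
#' temperature (stemp) and autumn precipitation (fprecip), each a linear
#' trend in a different direction plus smoothed noise. Offsets keep the
#' temperature and precipitation surfaces on plausible scales.
#'
#' @return a named list of gradient specifications.
#' @export
default_env_gradients <- function() {
  list(
    cti = list(trend_x = 2, trend_y = 0, noise_sd = 0.5, smooth = 8,
               offset = 8),
    hli = list(trend_x = 0, trend_y = -0.3, noise_sd = 0.1, smooth = 8,
               offset = 0.8),
    stemp = list(trend_x = -4, trend_y = -4, noise_sd = 1, smooth = 8,
                 offset = 24),
    fprecip = list(trend_x = 0, trend_y = 25, noise_sd = 4, smooth = 8,
                   offset = 30),
    summer_precip = list(trend_x = 30, trend_y = 0, noise_sd = 5, smooth = 8,
                         offset = 60),
    winter_tmin = list(trend_x = 3, trend_y = -3, noise_sd = 0.8, smooth = 8,
                       offset = -10)
  )
}

#' Default true gravity-model coefficients
#'
#' A temperature-moisture structure: flow declines with distance and
#' warmest-month temperature, increases with wetness (cti, autumn
#' precipitation); heat load reduces at-site production. Names ending in
#' `_site` are at-site terms evaluated at the edge origin node; the rest are
#' between-site edge medians.
#'
#' @return named numeric coefficient vector on the ln-flow scale.
#' @export
default_gravity_truth <- function() {
  c(intercept = 1.2, dist = -0.35, hli_site = -0.25, cti_site = 0.10,
    stemp = -0.60, cti = 0.20, fprecip = 0.25)
}
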