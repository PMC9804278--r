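#' Simulate structured genotypes with known truth
#'
#' Generates a site network on a synthetic landscape and an
#' individuals-by-SNPs genotype panel under the Balding-Nichols island
#' model: neutral locus `i` has ancestral frequency `p_i ~ Uniform(0.1,
#' 0.9)` and per-deme frequencies `Beta(p(1-F)/F, (1-p)(1-F)/F)` with
#' `F = target_fst`, so the expected multi-locus F_ST equals `F` by
#' construction. With `n_groups > 1` a two-level hierarchy is used
#' (groups at `fst_between`, demes within groups at `target_fst`).
#' Adaptive loci respond to the environment: the deme frequency is
#' `logistic(logit(p_i) + selection_strength * env_z)` plus small noise,
#' where `env_z` is the standardised site value of the locus's assigned
#' predictor. Genotypes are `Binomial(2, deme frequency)`, thinned to
#' missing at `missing_rate`, with Poisson read depths.
#'
#' @param config a [sim_config()].
#' @return a list with `gm` (a [geno_matrix()]), `truth` (adaptive locus
#'   ids and predictors, per-site allele frequencies, site table, group
#'   assignment, true parameters), `env` (per-site predictor tibble),
#'   `rasters` (the landscape stack) and `depths` (per-genotype depths).
#' @export
simulate_genotypes <- function(config = sim_config()) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  rasters <- make_landscape(config)
  sites <- place_sites(config)
  env <- extract_node_covariates(
    dplyr::rename(sites, id = site_id), rasters)
  env <- dplyr::rename(env, site_id = id)[, c("site_id",
                                              names(config$env_gradients))]

  S <- config$n_sites
  Ln <- config$n_neutral
  La <- config$n_adaptive
  L <- Ln + La

  set.seed(sub_seed(config$seed, "frequencies"))
  p_anc <- runif(L, 0.1, 0.9)
  F_w <- config$target_fst
  bn_draw <- function(p, F, n) {
    # Beta(p(1-F)/F, (1-p)(1-F)/F) per deme; F -> 0 degenerates to p
    if (F < 1e-12) return(matrix(rep(p, each = n), n, length(p)))
    a <- p * (1 - F) / F
    b <- (1 - p) * (1 - F) / F
    matrix(rbeta(n * length(p), rep(a, each = n), rep(b, each = n)),
           n, length(p))
  }

  groups <- if (config$n_groups > 1) {
    # spatially contiguous blocks along the west-east axis
    blocks <- rep(seq_len(config$n_groups),
                  each = ceiling(S / config$n_groups))[seq_len(S)]
    blocks[rank(sites$x, ties.method = "first")]
  } else {
    rep(1L, S)
  }
  freq <- matrix(NA_real_, S, L)
  if (config$n_groups > 1) {
    gfreq <- bn_draw(p_anc, config$fst_between, config$n_groups)
    gfreq <- pmin(pmax(gfreq, 0.01), 0.99)
    for (g in seq_len(config$n_groups)) {
      demes <- which(groups == g)
      for (l in seq_len(L)) {
        freq[demes, l] <- rbeta(length(demes),
                                gfreq[g, l] * (1 - F_w) / F_w,
                                (1 - gfreq[g, l]) * (1 - F_w) / F_w)
      }
    }
  } else {
    freq <- bn_draw(p_anc, F_w, S)
  }

  # adaptive loci: frequency tracks the assigned predictor
  adaptive_ids <- character(0)
  adaptive_pred <- character(0)
  predictors <- c("summer_precip", "fprecip", "winter_tmin")
  predictors <- predictors[predictors %in% names(env)]
  if (La > 0) {
    set.seed(sub_seed(config$seed, "adaptive"))
    for (k in seq_len(La)) {
      l <- Ln + k
      pred <- predictors[(k - 1L) %% length(predictors) + 1L]
      env_z <- as.vector(scale(env[[pred]]))
      f <- plogis(qlogis(p_anc[l]) + config$selection_strength * env_z) +
        rnorm(S, 0, config$adaptive_noise_sd)
      freq[, l] <- pmin(pmax(f, 0.005), 0.995)
      adaptive_pred <- c(adaptive_pred, pred)
    }
  }

  set.seed(sub_seed(config$seed, "genotypes"))
  n_tot <- S * config$n_ind_per_site
  site_of_ind <- rep(sites$site_id, each = config$n_ind_per_site)
  g <- matrix(rbinom(n_tot * L, 2L, prob = freq[rep(seq_len(S),
                                                    each = config$n_ind_per_site), ]),
              n_tot, L)
  snp_id <- sprintf("L%05d_1", seq_len(L))
  if (La > 0) adaptive_ids <- snp_id[Ln + seq_len(La)]
  colnames(g) <- snp_id
  rownames(g) <- sprintf("%s_i%02d", site_of_ind,
                         sequence(rep(config$n_ind_per_site, S)))

  depths <- NULL
  if (config$missing_rate > 0) {
    g[matrix(runif(length(g)) < config$missing_rate, nrow(g))] <- NA_integer_
  }
  depths <- matrix(rpois(length(g), config$depth_mean), nrow(g),
                   dimnames = dimnames(g))
  depths[is.na(g)] <- NA_integer_
  mean_depth <- colMeans(depths, na.rm = TRUE)
  mean_depth[is.nan(mean_depth)] <- NA_real_

  snp_meta <- tibble(
    snp_id = snp_id, locus_id = sub("_1$", "", snp_id), pos_in_locus = 1L,
    ref = "A", alt = "T", mean_depth = mean_depth
  )
  ind_meta <- tibble(ind_id = rownames(g), site_id = site_of_ind)
  gm <- geno_matrix(g, snp_meta = snp_meta, ind_meta = ind_meta,
                    sites = sites)

  truth <- list(
    adaptive_locus_ids = adaptive_ids,
    adaptive_predictor = setNames(adaptive_pred, adaptive_ids),
    site_freq = `dimnames<-`(freq, list(sites$site_id, snp_id)),
    sites = sites,
    groups = setNames(groups, sites$site_id),
    target_fst = config$target_fst,
    gravity_truth = config$gravity_truth,
    wf_ne = config$wf_ne
  )
  list(gm = gm, truth = truth, env = env, rasters = rasters,
       depths = depths)
}

# scatter sites uniformly with a minimum separation (rejection sampling)
place_sites <- function(config) {
  set.seed(sub_seed(config$seed, "sites"))
  S <- config$n_sites
  ext <- config$landscape_extent
  min_d <- ext / (2 * sqrt(S) + 2)
  xs <- ys <- numeric(0)
  tries <- 0
  while (length(xs) < S && tries < 20000) {
    tries <- tries + 1
    cand_x <- runif(1, 0.03 * ext, 0.97 * ext)
    cand_y <- runif(1, 0.03 * ext, 0.97 * ext)
    if (length(xs) == 0 ||
        min(sqrt((xs - cand_x)^2 + (ys - cand_y)^2)) >= min_d) {
      xs <- c(xs, cand_x)
      ys <- c(ys, cand_y)
    }
  }
  assert_that(length(xs) == S, "could not place sites with separation")
  tibble(
    site_id = sprintf("S%02d", seq_len(S)),
    x = xs, y = ys,
    region = "core",
    mu = sprintf("MU%02d", (seq_len(S) - 1L) %/% 3L + 1L)
  )
}

#' Simulate a Wright-Fisher population and genotype a sample
#'
#' Forward-time neutral simulation of one isolated diploid population of
#' constant size `true_ne` with free recombination between loci: each
#' generation every offspring draws two random parents and one allele per
#' locus from each. Initial allele frequencies are `Uniform(0.2, 0.8)` and
#' the population is run `4 * true_ne` generations (enough for the
#' equilibrium linkage disequilibrium that the LD-Ne method measures to
#' build up), after which `n_sample` individuals are genotyped.
#'
#' @param true_ne population size (the true Ne).
#' @param n_loci number of unlinked biallelic loci.
#' @param n_sample individuals to genotype (warns when above `true_ne`).
#' @param seed integer seed.
#' @param n_generations generations to run (default `4 * true_ne`).
#' @return a [geno_matrix()] with one site `"WF1"`; the per-generation mean
#'   expected heterozygosity is attached as attribute `het_trajectory`.
#' @export
simulate_wf_sample <- function(true_ne, n_loci, n_sample, seed = 1L,
                               n_generations = 4L * true_ne) {
  assert_that(is_count(true_ne), "true_ne must be a count")
  if (n_sample > true_ne)
    warning("n_sample exceeds true_ne; sampling with the whole population")
  if (n_loci < 50)
    warning("fewer than 50 loci: Ne estimate will be unstable")
  set.seed(sub_seed(seed, "wright_fisher"))
  N <- true_ne
  p0 <- runif(n_loci, 0.2, 0.8)
  A1 <- matrix(rbinom(N * n_loci, 1L, rep(p0, each = N)), N, n_loci)
  A2 <- matrix(rbinom(N * n_loci, 1L, rep(p0, each = N)), N, n_loci)
  het <- numeric(n_generations + 1L)
  pbar <- colMeans((A1 + A2) / 2)
  het[1] <- mean(2 * pbar * (1 - pbar))
  for (t in seq_len(n_generations)) {
    par1 <- sample.int(N, N, replace = TRUE)
    par2 <- sample.int(N, N, replace = TRUE)
    pick1 <- matrix(runif(N * n_loci) < 0.5, N, n_loci)
    pick2 <- matrix(runif(N * n_loci) < 0.5, N, n_loci)
    B1 <- ifelse(pick1, A1[par1, ], A2[par1, ])
    B2 <- ifelse(pick2, A1[par2, ], A2[par2, ])
    A1 <- B1; A2 <- B2
    pbar <- colMeans((A1 + A2) / 2)
    het[t + 1L] <- mean(2 * pbar * (1 - pbar))
  }
  take <- sample.int(N, min(n_sample, N))
  g <- A1[take, , drop = FALSE] + A2[take, , drop = FALSE]
  rownames(g) <- sprintf("wf_i%03d", seq_along(take))
  colnames(g) <- sprintf("wf_L%05d", seq_len(n_loci))
  gm <- geno_matrix(g, ind_meta = tibble(ind_id = rownames(g),
                                         site_id = "WF1"))
  attr(gm, "het_trajectory") <- het
  gm
}
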