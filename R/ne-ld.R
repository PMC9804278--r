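#' Configuration for LD-based effective population size
#'
#' @param pcrit_values allele-frequency screening thresholds; for each value
#'   an estimate is produced with SNPs whose within-site minor allele
#'   frequency falls below the threshold excluded entirely.
#' @param n_chromosome_pairs haploid chromosome number used by
#'   [chromosome_correct()] (13 for *Rana pretiosa*-like ranid karyotypes).
#' @param min_call_rate minimum within-site call rate for a SNP to be used.
#' @param max_loci cap on the number of SNPs entering the pairwise
#'   computation; when exceeded, loci are thinned deterministically (evenly
#'   spaced) to keep the locus-pair burden bounded.
#' @return an `ne_config` list.
#' @export
ne_config <- function(pcrit_values = c(0.05, 0.10), n_chromosome_pairs = 13L,
                      min_call_rate = 0.80, max_loci = 2000L) {
  assert_that(all(pcrit_values > 0 & pcrit_values < 0.5),
              "pcrit values must lie in (0, 0.5)")
  assert_that(is_count(n_chromosome_pairs), "chromosome pairs must be >= 1")
  structure(list(pcrit_values = pcrit_values,
                 n_chromosome_pairs = n_chromosome_pairs,
                 min_call_rate = min_call_rate,
                 max_loci = as.integer(max_loci)),
            class = "ne_config")
}

#' Correct an LD-Ne estimate for chromosome number
#'
#' Physical linkage among retained loci biases LD-based effective size
#' downward; the correction divides the raw estimate by
#' `0.098 + 0.219 * ln(n_chromosome_pairs)`. Infinite estimates stay
#' infinite.
#'
#' @param raw_ne raw point estimate (may be `Inf`).
#' @param n_chromosome_pairs haploid chromosome number, at least 1.
#' @return the corrected estimate.
#' @export
chromosome_correct <- function(raw_ne, n_chromosome_pairs = 13L) {
  assert_that(is.numeric(n_chromosome_pairs) && n_chromosome_pairs >= 1,
              "n_chromosome_pairs must be >= 1")
  raw_ne / (0.098 + 0.219 * log(n_chromosome_pairs))
}

# Waples sample-size component of r^2 and the drift inversion, both branch
# on whether the (harmonic mean) sample size reaches 30
expected_r2_sample <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2, 0.0018 + 0.907 / S + 4.44 / S^2)
}

waples_ne_inverse <- function(r2_drift, S) {
  if (!is.finite(r2_drift) || r2_drift <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2_drift
    if (disc < 0) return(Inf)
    (1 / 3 + sqrt(disc)) / (2 * r2_drift)
  } else {
    disc <- 0.308^2 - 2.08 * r2_drift
    if (disc < 0) return(Inf)
    (0.308 + sqrt(disc)) / (2 * r2_drift)
  }
}

# pairwise Burrows r^2 machinery: sufficient sums per locus pair from a
# genotype matrix with missing values
pair_sums <- function(G) {
  M <- !is.na(G)
  G0 <- G
  G0[!M] <- 0
  storage.mode(G0) <- "double"
  Ms <- matrix(as.double(M), nrow(M), ncol(M))
  list(
    N = crossprod(Ms),
    Sxy = crossprod(G0),
    Sx = crossprod(G0, Ms),      # sum of x over individuals called at both
    Sxx = crossprod(G0^2, Ms)
  )
}

# r^2 per pair from upper-triangle sufficient-sum vectors; returns NA where
# a pair is unusable (S < 2 or zero variance on a side)
r2_from_sums <- function(N, Sx, Sy, Sxy, Sxx, Syy) {
  ok <- N >= 2
  mx <- Sx / N
  my <- Sy / N
  cv <- Sxy / N - mx * my
  vx <- Sxx / N - mx^2
  vy <- Syy / N - my^2
  ok <- ok & vx > 0 & vy > 0
  r2 <- (N / (N - 1))^2 * cv^2 / (vx * vy)
  r2[!ok] <- NA_real_
  r2
}

# mean r^2, harmonic-mean S and the drift-attributable residual r^2
r2_drift_stat <- function(N, Sx, Sy, Sxy, Sxx, Syy) {
  r2 <- r2_from_sums(N, Sx, Sy, Sxy, Sxx, Syy)
  use <- !is.na(r2)
  if (!any(use)) return(NULL)
  s_harm <- 1 / mean(1 / N[use])
  r2_mean <- mean(r2[use])
  list(r2_mean = r2_mean, s_harm = s_harm,
       r2_drift = r2_mean - expected_r2_sample(s_harm),
       n_pairs = sum(use))
}

#' LD-method effective population size for one site
#'
#' Estimates contemporary effective size from the inter-locus linkage
#' disequilibrium in a single site sample. For every locus pair, the squared
#' Burrows composite correlation of unphased genotype codes is computed
#' (with Weir's small-sample factor `S/(S-1)`); the mean across pairs, minus
#' the sample-size expectation `E(r^2_S)` evaluated at the harmonic-mean
#' pairwise sample size, leaves the drift-attributable disequilibrium, which
#' is inverted to an effective size (Waples-style inversion; non-positive
#' residual disequilibrium maps to an infinite estimate). Confidence
#' intervals are by delete-one-individual jackknife on the residual
#' disequilibrium, mapped through the same inversion. Point estimates and
#' CIs are also reported after division by the chromosome-number correction
#' of [chromosome_correct()].
#'
#' @param gm a [geno_matrix()].
#' @param site_id site to estimate (must exist in the registry).
#' @param cfg an [ne_config()].
#' @return a tibble with one row per Pcrit value: sample sizes, loci and
#'   pairs used, mean `r2`, its sampling expectation, raw and corrected Ne
#'   with jackknife CI bounds (`Inf` allowed).
#' @export
estimate_ne_ld <- function(gm, site_id, cfg = ne_config()) {
  assert_that(site_id %in% gm$sites$site_id,
              paste0("unknown site: ", site_id))
  rows <- which(site_of(gm) == site_id)
  assert_that(length(rows) >= 5, "site needs at least 5 genotyped individuals")
  G <- gm$genotypes[rows, , drop = FALSE]

  call_rate <- colMeans(!is.na(G))
  n_called <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p, 1 - p)

  out <- vector("list", length(cfg$pcrit_values))
  for (k in seq_along(cfg$pcrit_values)) {
    pcrit <- cfg$pcrit_values[k]
    keep <- call_rate >= cfg$min_call_rate & maf >= pcrit & n_called >= 2
    idx <- which(keep)
    if (length(idx) > cfg$max_loci) {
      idx <- idx[round(seq(1, length(idx), length.out = cfg$max_loci))]
    }
    assert_that(length(idx) >= 2,
                sprintf("fewer than 2 usable loci at Pcrit=%.2f", pcrit))
    if (length(idx) < 50)
      warning(sprintf("only %d loci at Pcrit=%.2f: Ne estimate unstable",
                      length(idx), pcrit))
    Gk <- G[, idx, drop = FALSE]
    L <- ncol(Gk)
    ps <- pair_sums(Gk)
    ut <- pair_index(L)
    N <- ps$N[ut]; Sxy <- ps$Sxy[ut]
    Sx <- ps$Sx[ut]; Sy <- t(ps$Sx)[ut]
    Sxx <- ps$Sxx[ut]; Syy <- t(ps$Sxx)[ut]

    full <- r2_drift_stat(N, Sx, Sy, Sxy, Sxx, Syy)
    assert_that(!is.null(full), "no usable locus pairs")
    ne_raw <- waples_ne_inverse(full$r2_drift, full$s_harm)

    # delete-one-individual jackknife on the residual disequilibrium
    n <- nrow(Gk)
    ia <- ut[, 1]; ib <- ut[, 2]
    theta <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      g <- Gk[i, ]
      m <- as.double(!is.na(g))
      g0 <- ifelse(is.na(g), 0, as.double(g))
      dN <- m[ia] * m[ib]
      jk <- r2_drift_stat(N - dN,
                          Sx - g0[ia] * m[ib], Sy - m[ia] * g0[ib],
                          Sxy - g0[ia] * g0[ib],
                          Sxx - g0[ia]^2 * m[ib], Syy - m[ia] * g0[ib]^2)
      if (!is.null(jk)) theta[i] <- jk$r2_drift
    }
    theta <- theta[is.finite(theta)]
    n_jk <- length(theta)
    if (n_jk >= 2) {
      se <- sqrt((n_jk - 1) / n_jk * sum((theta - mean(theta))^2))
      lo_r2 <- full$r2_drift - qnorm(0.975) * se
      hi_r2 <- full$r2_drift + qnorm(0.975) * se
      ci_hi <- waples_ne_inverse(lo_r2, full$s_harm)   # smaller LD -> larger Ne
      ci_lo <- waples_ne_inverse(hi_r2, full$s_harm)
    } else {
      ci_lo <- NA_real_; ci_hi <- NA_real_
    }
    # guarantee ordering lo <= point <= hi under the monotone inversion
    ci_lo <- min(ci_lo, ne_raw, na.rm = TRUE)
    ci_hi <- max(ci_hi, ne_raw, na.rm = TRUE)

    div <- 0.098 + 0.219 * log(cfg$n_chromosome_pairs)
    out[[k]] <- tibble(
      site_id = site_id, pcrit = pcrit,
      n_ind = n, s_harmonic = full$s_harm,
      n_loci = L, n_pairs = full$n_pairs,
      r2_mean = full$r2_mean, r2_expected = expected_r2_sample(full$s_harm),
      r2_drift = full$r2_drift,
      ne_raw = ne_raw, ne_raw_lo = ci_lo, ne_raw_hi = ci_hi,
      ne_corrected = ne_raw / div,
      ne_lo = ci_lo / div, ne_hi = ci_hi / div
    )
  }
  dplyr::bind_rows(out)
}

#' LD-Ne estimates for every adequately sampled site
#'
#' @param gm a [geno_matrix()].
#' @param cfg an [ne_config()].
#' @param min_n minimum site sample size to attempt an estimate.
#' @return a tibble of [estimate_ne_ld()] rows across sites.
#' @export
estimate_ne_all_sites <- function(gm, cfg = ne_config(), min_n = 11L) {
  sizes <- table(site_of(gm))
  use <- names(sizes)[sizes >= min_n]
  dplyr::bind_rows(lapply(use, function(s) estimate_ne_ld(gm, s, cfg)))
}
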