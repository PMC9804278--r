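#' Nei's standard genetic distance between sites
#'
#' Nei (1972) standard distance from biallelic allele frequencies:
#' with per-locus homozygosity sums `J_x = p^2 + q^2`, `J_y` likewise and
#' cross-product `J_xy = p_x p_y + q_x q_y`, each averaged over loci, the
#' normalised identity is `I = J_xy / sqrt(J_x J_y)` and `D = -ln(I)`
#' (infinite when `I = 0`). Loci without calls on either side of a pair are
#' dropped for that pair.
#'
#' @param gm a [geno_matrix()].
#' @return a `pairwise_matrix` of kind `"nei_d"`; the normalised identity is
#'   attached as element `identity`.
#' @export
nei_distance_matrix <- function(gm) {
  counts <- site_geno_counts(gm)
  sites <- rownames(counts$n)
  assert_that(length(sites) >= 2, "need at least two sites")
  S <- length(sites)
  p <- counts$alt / (2 * counts$n)

  D <- I_m <- matrix(0, S, S, dimnames = list(sites, sites))
  nloci <- matrix(0L, S, S, dimnames = list(sites, sites))
  diag(I_m) <- 1
  pairs <- pair_index(S)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    use <- counts$n[i, ] > 0 & counts$n[j, ] > 0
    if (!any(use)) {
      warning(sprintf("no shared loci for pair %s-%s", sites[i], sites[j]))
      D[i, j] <- D[j, i] <- NA_real_
      I_m[i, j] <- I_m[j, i] <- NA_real_
      next
    }
    px <- p[i, use]; py <- p[j, use]
    jx <- mean(px^2 + (1 - px)^2)
    jy <- mean(py^2 + (1 - py)^2)
    jxy <- mean(px * py + (1 - px) * (1 - py))
    I <- jxy / sqrt(jx * jy)
    I_m[i, j] <- I_m[j, i] <- I
    D[i, j] <- D[j, i] <- if (I <= 0) Inf else -log(I)
    nloci[i, j] <- nloci[j, i] <- sum(use)
  }
  out <- pairwise_matrix(D, kind = "nei_d", n_loci = nloci)
  out$identity <- I_m
  out
}
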