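#' Exact test of Hardy-Weinberg proportions for a biallelic SNP
#'
#' Two-sided exact test on the heterozygote count conditional on the observed
#' allele counts (the standard SNP exact test): the p-value is the total
#' probability of all heterozygote counts whose conditional probability does
#' not exceed that of the observed count. No mid-p adjustment.
#'
#' @param n_aa,n_ab,n_bb genotype counts (homozygous reference,
#'   heterozygous, homozygous alternate).
#' @return the exact p-value; `1` when fewer than two individuals are
#'   genotyped or the SNP is monomorphic in the sample.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 2) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each het count given allele counts
  lp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n - (rare + hets) / 2) + 1) + hets * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}
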