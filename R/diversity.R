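#' Per-site genetic diversity
#'
#' Computes, for every site, observed heterozygosity (mean fraction of
#' heterozygous calls over SNPs with at least one genotype), unbiased
#' expected heterozygosity `(2n/(2n-1)) * 2p(1-p)` averaged over SNPs,
#' nucleotide diversity (the sum of unbiased per-SNP heterozygosities divided
#' by the assayed sequence length), and the count of private alleles
#' (alleles observed in that site only).
#'
#' Nucleotide diversity from reduced-representation data depends on the total
#' assayed length, not only the variant positions, which is why the
#' denominator is explicit: with 90 bp RAD loci, `assayed_length` is roughly
#' `n_loci * 90`.
#'
#' @param gm a [geno_matrix()].
#' @param assayed_length total assayed sequence length in bp used as the
#'   denominator for nucleotide diversity.
#' @return a tibble with one row per site: `site_id`, `n`, `ho`, `he`, `pi`,
#'   `private_alleles`, `assayed_length`.
#' @export
site_diversity <- function(gm, assayed_length = 90 * n_snp(gm)) {
  assert_that(is.numeric(assayed_length) && assayed_length > 0,
              "assayed_length must be positive")
  counts <- site_geno_counts(gm)
  n <- counts$n
  p <- counts$alt / (2 * n)

  ho_site <- he_site <- pi_site <- numeric(nrow(n))
  for (s in seq_len(nrow(n))) {
    use <- n[s, ] > 0
    ho_site[s] <- mean(counts$het[s, use] / n[s, use])
    nn <- n[s, use]
    pp <- p[s, use]
    he_snp <- (2 * nn / (2 * nn - 1)) * 2 * pp * (1 - pp)
    he_site[s] <- mean(he_snp)
    pi_site[s] <- sum(he_snp) / assayed_length
  }

  # private alleles: allele observed here and at no other site
  has_alt <- counts$alt > 0
  has_ref <- counts$alt < 2 * n & n > 0
  priv <- integer(nrow(n))
  for (s in seq_len(nrow(n))) {
    others_alt <- colSums(has_alt[-s, , drop = FALSE]) > 0
    others_ref <- colSums(has_ref[-s, , drop = FALSE]) > 0
    priv[s] <- sum(has_alt[s, ] & !others_alt) + sum(has_ref[s, ] & !others_ref)
  }

  sizes <- table(factor(site_of(gm), levels = rownames(n)))
  tibble(
    site_id = rownames(n),
    n = as.integer(sizes),
    ho = ho_site, he = he_site, pi = pi_site,
    private_alleles = priv,
    assayed_length = assayed_length
  )
}

#' Summarise a column of per-site statistics
#'
#' Mean, median, minimum and maximum of a numeric vector, with optional
#' rounding -- the shape used for headline summaries of per-site tables
#' (mean and median effective size, mean nucleotide diversity, and so on).
#'
#' @param values numeric vector; non-finite entries are dropped.
#' @param digits optional number of digits to round to; `signif_digits`
#'   rounds to significant figures instead (applied after `digits`).
#' @param signif_digits optional significant figures.
#' @return a one-row tibble: `n`, `mean`, `median`, `min`, `max`.
#' @export
summarize_column <- function(values, digits = NULL, signif_digits = NULL) {
  v <- values[is.finite(values)]
  assert_that(length(v) >= 1, "summarize_column needs at least 1 finite value")
  out <- tibble(n = length(v), mean = mean(v), median = median(v),
                min = min(v), max = max(v))
  num <- c("mean", "median", "min", "max")
  if (!is.null(digits)) out[num] <- lapply(out[num], round, digits = digits)
  if (!is.null(signif_digits))
    out[num] <- lapply(out[num], signif, digits = signif_digits)
  out
}
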