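#' Weir-Cockerham variance components for biallelic SNPs
#'
#' Internal: per-locus a, b, c components for an arbitrary number of
#' populations, from per-site genotyped counts `n`, alternate-allele
#' frequencies `p` and observed heterozygote frequencies `h` (all sites x
#' SNPs matrices). Sites with no calls at a locus are excluded locus-wise.
#'
#' @noRd
wc_components <- function(n, p, h) {
  used <- n > 0
  r <- colSums(used)
  n_tot <- colSums(n)
  n_bar <- n_tot / r
  n2 <- colSums(n^2)
  n_c <- (n_tot - n2 / n_tot) / (r - 1)
  p_bar <- colSums(n * p, na.rm = TRUE) / n_tot
  s2 <- colSums(n * (p - rep(p_bar, each = nrow(p)))^2, na.rm = TRUE) /
    ((r - 1) * n_bar)
  h_bar <- colSums(n * h, na.rm = TRUE) / n_tot

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, p_bar = p_bar, r = r)
}

#' Pairwise Weir-Cockerham F_ST between sites
#'
#' Multi-locus theta for every pair of sites, computed as the ratio of sums
#' across loci of the Weir-Cockerham (1984) variance components
#' `sum(a) / sum(a + b + c)`. Loci monomorphic within a pair, or with no
#' calls on one side, are skipped for that pair. Small negative estimates
#' are retained (not truncated).
#'
#' @param gm a [geno_matrix()]; at least two sites with two or more
#'   genotyped individuals each.
#' @return a `pairwise_matrix` object (see [pairwise_matrix()]) of kind
#'   `"fst"`; cells for pairs sharing no usable loci are `NA` with a warning.
#' @export
pairwise_fst_wc <- function(gm) {
  counts <- site_geno_counts(gm)
  sites <- rownames(counts$n)
  assert_that(length(sites) >= 2, "need at least two sites")
  S <- length(sites)
  theta <- matrix(0, S, S, dimnames = list(sites, sites))
  nloci <- matrix(0L, S, S, dimnames = list(sites, sites))
  p_all <- counts$alt / (2 * counts$n)
  h_all <- counts$het / counts$n

  pairs <- pair_index(S)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    n <- counts$n[c(i, j), , drop = FALSE]
    both <- n[1, ] > 0 & n[2, ] > 0
    p <- p_all[c(i, j), , drop = FALSE]
    alt <- colSums(counts$alt[c(i, j), , drop = FALSE])
    poly <- both & alt > 0 & alt < colSums(2 * n)
    if (!any(poly)) {
      warning(sprintf("no usable loci for pair %s-%s", sites[i], sites[j]))
      theta[i, j] <- theta[j, i] <- NA_real_
      next
    }
    comp <- wc_components(n[, poly, drop = FALSE], p[, poly, drop = FALSE],
                          h_all[c(i, j), poly, drop = FALSE])
    denom <- sum(comp$a + comp$b + comp$c)
    theta[i, j] <- theta[j, i] <- sum(comp$a) / denom
    nloci[i, j] <- nloci[j, i] <- sum(poly)
  }
  pairwise_matrix(theta, kind = "fst", n_loci = nloci)
}

#' Multi-population Weir-Cockerham F_ST
#'
#' Global theta over all sites, ratio-of-sums across loci. Loci monomorphic
#' overall are skipped.
#'
#' @param gm a [geno_matrix()].
#' @return a single numeric theta estimate.
#' @export
global_fst_wc <- function(gm) {
  counts <- site_geno_counts(gm)
  assert_that(nrow(counts$n) >= 2, "need at least two sites")
  n <- counts$n
  p <- counts$alt / (2 * n)
  h <- counts$het / n
  ac <- colSums(counts$alt)
  poly <- ac > 0 & ac < colSums(2 * n) & colSums(n > 0) >= 2
  comp <- wc_components(n[, poly, drop = FALSE], p[, poly, drop = FALSE],
                        h[, poly, drop = FALSE])
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Symmetric site-by-site matrix of a pairwise statistic
#'
#' Container for pairwise differentiation results (`fst` or `nei_d`), with a
#' zero diagonal and a per-cell count of loci used.
#'
#' @param values symmetric numeric matrix with site names.
#' @param kind `"fst"` or `"nei_d"`.
#' @param n_loci matrix of locus counts per cell (optional).
#' @return a `pairwise_matrix` object.
#' @export
pairwise_matrix <- function(values, kind = c("fst", "nei_d"), n_loci = NULL) {
  kind <- match.arg(kind)
  assert_that(is.matrix(values) && nrow(values) == ncol(values),
              "values must be a square matrix")
  diag(values) <- 0
  structure(list(values = values, kind = kind, n_loci = n_loci),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix:%s> %d sites\n", x$kind, nrow(x$values)))
  invisible(x)
}

#' Tidy a pairwise matrix into long format
#'
#' @param x a [pairwise_matrix()].
#' @param ... unused.
#' @return a tibble with `site_a`, `site_b` (i < j pairs only), `value`, and
#'   `n_loci` when recorded.
#' @method tidy pairwise_matrix
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  idx <- pair_index(nrow(x$values))
  out <- tibble(
    site_a = rownames(x$values)[idx[, 1]],
    site_b = colnames(x$values)[idx[, 2]],
    value = x$values[idx]
  )
  if (!is.null(x$n_loci)) out$n_loci <- x$n_loci[idx]
  out
}

#' Mean cross-group values of a pairwise statistic
#'
#' Averages the cells of a pairwise matrix that connect a focal set of sites
#' with all remaining sites -- used, for example, to summarise how divergent
#' a region is from the rest of a study area.
#'
#' @param pm a [pairwise_matrix()].
#' @param focal_sites character vector of site ids forming the focal group.
#' @return a one-row tibble: `n_pairs`, `mean`, `min`, `max`.
#' @export
cross_group_fst_summary <- function(pm, focal_sites) {
  v <- pm$values
  assert_that(all(focal_sites %in% rownames(v)), "unknown focal site id")
  others <- setdiff(rownames(v), focal_sites)
  assert_that(length(others) > 0, "focal set covers every site")
  cells <- v[focal_sites, others, drop = FALSE]
  cells <- cells[is.finite(cells)]
  tibble(n_pairs = length(cells), mean = mean(cells),
         min = min(cells), max = max(cells))
}
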