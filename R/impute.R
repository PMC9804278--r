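#' Mode imputation of missing genotypes within sites
#'
#' Replaces each missing call with the most frequent genotype among the
#' called individuals of the same site; SNPs with no calls at a site fall
#' back to the global mode. Ties between modes resolve to the lower
#' genotype code. A deliberately simple, deterministic imputer: ordination
#' inputs must be complete, and anything cleverer belongs upstream.
#'
#' @param gm a [geno_matrix()].
#' @return the complete individuals x SNPs integer matrix.
#' @export
impute_missing_mode <- function(gm) {
  g <- gm$genotypes
  if (!anyNA(g)) return(g)
  zero_call <- colSums(!is.na(g)) == 0
  assert_that(!any(zero_call),
              "SNP(s) with zero calls anywhere; filter before imputing")
  rows <- site_rows(gm)
  # genotype-class counts per site via indicator sums
  mode_code <- function(counts) {
    # counts: 3 x nsnp matrix of genotype-class counts; ties -> lower code
    (apply(counts, 2, which.max) - 1L)
  }
  glob <- rbind(colSums(g == 0L, na.rm = TRUE),
                colSums(g == 1L, na.rm = TRUE),
                colSums(g == 2L, na.rm = TRUE))
  global_mode <- mode_code(glob)
  for (s in seq_along(rows)) {
    gs <- g[rows[[s]], , drop = FALSE]
    na_cols <- which(colSums(is.na(gs)) > 0)
    if (length(na_cols) == 0) next
    cnt <- rbind(colSums(gs[, na_cols, drop = FALSE] == 0L, na.rm = TRUE),
                 colSums(gs[, na_cols, drop = FALSE] == 1L, na.rm = TRUE),
                 colSums(gs[, na_cols, drop = FALSE] == 2L, na.rm = TRUE))
    fill <- mode_code(cnt)
    none <- colSums(cnt) == 0
    fill[none] <- global_mode[na_cols[none]]
    for (k in seq_along(na_cols)) {
      j <- na_cols[k]
      miss <- is.na(gs[, j])
      g[rows[[s]][miss], j] <- fill[k]
    }
  }
  g
}
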