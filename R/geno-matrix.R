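#' Genotype matrix container
#'
#' The substrate of every genetic computation in the package: an
#' individuals-by-SNPs integer matrix of alternate-allele counts (0, 1, 2 or
#' `NA` for a missing call) together with per-SNP metadata, per-individual
#' metadata, and a site registry. Lightweight by design; all statistics
#' functions accept it and return tibbles.
#'
#' @param genotypes integer matrix, rows = individuals, cols = SNPs, entries
#'   in `{0, 1, 2, NA}`. Row and column names are used as individual and SNP
#'   ids when metadata is not supplied.
#' @param snp_meta tibble with one row per SNP: `snp_id`, `locus_id`,
#'   `pos_in_locus`, `ref`, `alt`, `mean_depth`. Missing columns are filled
#'   with defaults.
#' @param ind_meta tibble with one row per individual: `ind_id`, `site_id`.
#' @param sites site registry tibble: `site_id`, and optionally `x`, `y`
#'   (projected metres), `region`, `mu`. Built from `ind_meta` when absent.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(genotypes, snp_meta = NULL, ind_meta = NULL,
                        sites = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- genotypes[!is.na(genotypes)]
  assert_that(all(bad %in% 0:2), "genotype codes must be 0, 1, 2 or NA")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  assert_that(!anyDuplicated(colnames(genotypes)), "SNP ids must be unique")
  assert_that(!anyDuplicated(rownames(genotypes)),
              "individual ids must be unique")

  if (is.null(ind_meta)) {
    ind_meta <- tibble(ind_id = rownames(genotypes), site_id = "site1")
  }
  ind_meta <- as_tibble(ind_meta)
  assert_that(all(c("ind_id", "site_id") %in% names(ind_meta)),
              "ind_meta needs columns ind_id and site_id")
  assert_that(setequal(ind_meta$ind_id, rownames(genotypes)),
              "ind_meta does not match genotype rows")
  ind_meta <- ind_meta[match(rownames(genotypes), ind_meta$ind_id), ]

  if (is.null(snp_meta)) {
    snp_meta <- tibble(
      snp_id = colnames(genotypes),
      locus_id = colnames(genotypes),
      pos_in_locus = 1L,
      ref = "A", alt = "T",
      mean_depth = NA_real_
    )
  }
  snp_meta <- as_tibble(snp_meta)
  assert_that("snp_id" %in% names(snp_meta), "snp_meta needs column snp_id")
  if (is.null(snp_meta$locus_id)) snp_meta$locus_id <- snp_meta$snp_id
  if (is.null(snp_meta$pos_in_locus)) snp_meta$pos_in_locus <- 1L
  if (is.null(snp_meta$mean_depth)) snp_meta$mean_depth <- NA_real_
  assert_that(setequal(snp_meta$snp_id, colnames(genotypes)),
              "snp_meta does not match genotype columns")
  snp_meta <- snp_meta[match(colnames(genotypes), snp_meta$snp_id), ]

  if (is.null(sites)) {
    sites <- tibble(site_id = unique(ind_meta$site_id))
  }
  sites <- as_tibble(sites)
  assert_that(all(ind_meta$site_id %in% sites$site_id),
              "every individual's site_id must resolve in the site registry")

  structure(
    list(genotypes = genotypes, snp_meta = snp_meta, ind_meta = ind_meta,
         sites = sites),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d SNPs, %d sites, %.1f%% missing\n",
    nrow(x$genotypes), ncol(x$genotypes), nrow(x$sites),
    100 * mean(is.na(x$genotypes))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$genotypes)

n_ind <- function(gm) nrow(gm$genotypes)
n_snp <- function(gm) ncol(gm$genotypes)

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param gm a [geno_matrix()].
#' @param inds individual ids (or logical/integer index) to keep.
#' @param snps SNP ids (or logical/integer index) to keep.
#' @return a `geno_matrix` restricted to the selection; the site registry is
#'   restricted to sites that retain at least one individual.
#' @export
gm_subset <- function(gm, inds = NULL, snps = NULL) {
  g <- gm$genotypes
  keep_i <- if (is.null(inds)) seq_len(nrow(g)) else inds
  keep_s <- if (is.null(snps)) seq_len(ncol(g)) else snps
  g <- g[keep_i, keep_s, drop = FALSE]
  im <- gm$ind_meta[match(rownames(g), gm$ind_meta$ind_id), ]
  sm <- gm$snp_meta[match(colnames(g), gm$snp_meta$snp_id), ]
  st <- gm$sites[gm$sites$site_id %in% unique(im$site_id), ]
  geno_matrix(g, snp_meta = sm, ind_meta = im, sites = st)
}

# site id of every row of the genotype matrix
site_of <- function(gm) gm$ind_meta$site_id

# list of row indices per site, in registry order for sites with individuals
site_rows <- function(gm) {
  split(seq_len(n_ind(gm)), factor(site_of(gm), levels = gm$sites$site_id),
        drop = TRUE)
}

#' Per-site alternate-allele frequencies
#'
#' @param gm a [geno_matrix()].
#' @param min_n minimum number of genotyped individuals for a frequency to be
#'   reported (otherwise `NA`).
#' @return a sites x SNPs numeric matrix of alternate-allele frequencies.
#' @export
site_allele_freq <- function(gm, min_n = 1L) {
  rows <- site_rows(gm)
  g <- gm$genotypes
  out <- matrix(NA_real_, length(rows), ncol(g),
                dimnames = list(names(rows), colnames(g)))
  for (s in seq_along(rows)) {
    gs <- g[rows[[s]], , drop = FALSE]
    n <- colSums(!is.na(gs))
    p <- colSums(gs, na.rm = TRUE) / (2 * n)
    p[n < min_n] <- NA_real_
    out[s, ] <- p
  }
  out
}

# per-site genotyped counts (sites x SNPs) and observed-heterozygote counts
site_geno_counts <- function(gm) {
  rows <- site_rows(gm)
  g <- gm$genotypes
  n <- het <- alt <- matrix(0, length(rows), ncol(g),
                            dimnames = list(names(rows), colnames(g)))
  for (s in seq_along(rows)) {
    gs <- g[rows[[s]], , drop = FALSE]
    n[s, ] <- colSums(!is.na(gs))
    het[s, ] <- colSums(gs == 1L, na.rm = TRUE)
    alt[s, ] <- colSums(gs, na.rm = TRUE)
  }
  list(n = n, het = het, alt = alt)
}

# global minor allele count per SNP
global_mac <- function(gm) {
  g <- gm$genotypes
  n2 <- 2L * colSums(!is.na(g))
  ac <- colSums(g, na.rm = TRUE)
  pmin(ac, n2 - ac)
}
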