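#' Filtering configuration for the post-assembly SNP cascade
#'
#' Defaults follow common practice for RADseq SNP panels in small, structured
#' amphibian populations: individuals with more than 55% missing genotypes
#' are dropped; SNPs must be present at every site, reach a global minor
#' allele count of at least 10, have mean depth between 6 and 100, be called
#' in at least 80% of individuals, and sit on loci with at most 7 SNPs; one
#' SNP per locus is kept (highest MAC, ties broken by smallest position);
#' SNPs out of Hardy-Weinberg proportions (p < 0.05) in 5 or more
#' well-sampled sites, or heterozygous in every genotyped individual at any
#' adequately sampled site (paralogue signature), are removed.
#'
#' @param max_ind_missing maximum tolerated per-individual missingness.
#' @param min_global_mac minimum global minor allele count (a SNP is kept
#'   when MAC is at least this value).
#' @param depth_range inclusive bounds on per-SNP mean depth.
#' @param min_locus_call_rate minimum fraction of individuals genotyped.
#' @param max_snps_per_locus loci carrying more SNPs are removed whole.
#' @param hwe_alpha per-site significance level of the HWE exact test.
#' @param hwe_min_sites number of deviating sites required for removal.
#' @param hwe_site_min_n minimum site sample size for the HWE screen.
#' @param allhet_site_min_n minimum genotyped individuals at a site for the
#'   all-heterozygote screen.
#' @param min_variable_sites_rda minimum number of sites in which a SNP must
#'   be polymorphic to enter redundancy-analysis scans.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_ind_missing = 0.55,
                          min_global_mac = 10L,
                          depth_range = c(6, 100),
                          min_locus_call_rate = 0.80,
                          max_snps_per_locus = 7L,
                          hwe_alpha = 0.05,
                          hwe_min_sites = 5L,
                          hwe_site_min_n = 10L,
                          allhet_site_min_n = 7L,
                          min_variable_sites_rda = 3L) {
  assert_that(is_fraction(max_ind_missing, 0, 1), "max_ind_missing in (0,1)")
  assert_that(is_count(min_global_mac), "min_global_mac must be a count")
  assert_that(length(depth_range) == 2 && depth_range[1] <= depth_range[2],
              "depth_range must be [lo, hi]")
  assert_that(is_fraction(min_locus_call_rate, 0, 1),
              "min_locus_call_rate in (0,1)")
  assert_that(is_count(max_snps_per_locus), "max_snps_per_locus is a count")
  assert_that(is_fraction(hwe_alpha, 0, 1), "hwe_alpha in (0,1)")
  structure(list(
    max_ind_missing = max_ind_missing, min_global_mac = min_global_mac,
    depth_range = depth_range, min_locus_call_rate = min_locus_call_rate,
    max_snps_per_locus = max_snps_per_locus, hwe_alpha = hwe_alpha,
    hwe_min_sites = hwe_min_sites, hwe_site_min_n = hwe_site_min_n,
    allhet_site_min_n = allhet_site_min_n,
    min_variable_sites_rda = min_variable_sites_rda
  ), class = "filter_config")
}

#' Apply the post-assembly SNP filter cascade
#'
#' Runs the fixed sequence of marker and individual filters described in
#' [filter_config()], in order: (1) high-missingness individuals; (2) SNPs
#' absent from one or more sites; (3) global MAC; (4) mean-depth bounds;
#' (5) call rate; (6) over-dense loci; (7) one SNP per locus; (8) HWE
#' deviation across sites; (9) all-heterozygote (paralogue) screen. Each step
#' is recorded in a report whose removed/remaining counts always reconcile.
#'
#' @param gm a [geno_matrix()].
#' @param cfg a [filter_config()].
#' @return a list with elements `gm` (the filtered matrix) and `report`
#'   (a tibble with one row per step).
#' @export
apply_filter_cascade <- function(gm, cfg = filter_config()) {
  assert_that(inherits(gm, "geno_matrix"), "gm must be a geno_matrix")
  report <- list()
  note <- function(step, snps_removed, inds_removed, gm) {
    report[[length(report) + 1]] <<- tibble(
      step = step, snps_removed = snps_removed, inds_removed = inds_removed,
      snps_left = n_snp(gm), inds_left = n_ind(gm)
    )
    if (n_snp(gm) == 0 || n_ind(gm) == 0)
      stop(sprintf("filter cascade: no data left after step '%s'", step),
           call. = FALSE)
  }

  # (1) individuals with excess missingness
  miss <- rowMeans(is.na(gm$genotypes))
  keep <- miss <= cfg$max_ind_missing
  n_rm <- sum(!keep)
  if (n_rm > 0) gm <- gm_subset(gm, inds = which(keep))
  note("individual_missingness", 0L, n_rm, gm)

  # (2) SNP present (>=1 call) at every site
  counts <- site_geno_counts(gm)
  keep <- colSums(counts$n > 0) == nrow(counts$n)
  gm <- drop_snps(gm, keep, "common_across_sites")
  note("common_across_sites", sum(!keep), 0L, gm)

  # (3) global minor allele count
  keep <- global_mac(gm) >= cfg$min_global_mac
  gm <- drop_snps(gm, keep, "global_mac")
  note("global_mac", sum(!keep), 0L, gm)

  # (4) mean depth bounds (skipped for SNPs without depth information)
  md <- gm$snp_meta$mean_depth
  keep <- is.na(md) | (md >= cfg$depth_range[1] & md <= cfg$depth_range[2])
  gm <- drop_snps(gm, keep, "mean_depth")
  note("mean_depth", sum(!keep), 0L, gm)

  # (5) call rate
  keep <- colMeans(!is.na(gm$genotypes)) >= cfg$min_locus_call_rate
  gm <- drop_snps(gm, keep, "call_rate")
  note("call_rate", sum(!keep), 0L, gm)

  # (6) loci with too many SNPs removed whole
  per_locus <- table(gm$snp_meta$locus_id)
  bad_loci <- names(per_locus)[per_locus > cfg$max_snps_per_locus]
  keep <- !(gm$snp_meta$locus_id %in% bad_loci)
  gm <- drop_snps(gm, keep, "snps_per_locus")
  note("snps_per_locus", sum(!keep), 0L, gm)

  # (7) one SNP per locus: highest MAC, ties -> smallest position-in-locus
  mac <- global_mac(gm)
  ord <- order(gm$snp_meta$locus_id, -mac, gm$snp_meta$pos_in_locus)
  first <- !duplicated(gm$snp_meta$locus_id[ord])
  keep <- logical(n_snp(gm))
  keep[ord[first]] <- TRUE
  gm <- drop_snps(gm, keep, "one_snp_per_locus")
  note("one_snp_per_locus", sum(!keep), 0L, gm)

  # (8) HWE deviation in >= hwe_min_sites sites (sites with enough samples)
  keep <- !hwe_flagged(gm, cfg)
  gm <- drop_snps(gm, keep, "hwe")
  note("hwe", sum(!keep), 0L, gm)

  # (9) all-heterozygote screen at adequately genotyped sites
  counts <- site_geno_counts(gm)
  allhet <- counts$n >= cfg$allhet_site_min_n & counts$het == counts$n
  keep <- colSums(allhet) == 0
  gm <- drop_snps(gm, keep, "all_heterozygote")
  note("all_heterozygote", sum(!keep), 0L, gm)

  list(gm = gm, report = dplyr::bind_rows(report))
}

drop_snps <- function(gm, keep, step = "filter") {
  if (!any(keep))
    stop(sprintf("filter cascade: no data left after step '%s'", step),
         call. = FALSE)
  if (all(keep)) gm else gm_subset(gm, snps = which(keep))
}

# TRUE for SNPs deviating from HWE (p < alpha) in >= hwe_min_sites sites,
# evaluated only at sites whose total sample size meets hwe_site_min_n
hwe_flagged <- function(gm, cfg) {
  rows <- site_rows(gm)
  sizes <- lengths(rows)
  use <- sizes >= cfg$hwe_site_min_n
  if (!any(use)) return(rep(FALSE, n_snp(gm)))
  n_dev <- rep(0L, n_snp(gm))
  for (s in which(use)) {
    gs <- gm$genotypes[rows[[s]], , drop = FALSE]
    n_ab <- colSums(gs == 1L, na.rm = TRUE)
    n_bb <- colSums(gs == 2L, na.rm = TRUE)
    n_aa <- colSums(gs == 0L, na.rm = TRUE)
    p <- vapply(seq_len(ncol(gs)),
                function(j) hwe_exact_test(n_aa[j], n_ab[j], n_bb[j]),
                numeric(1))
    n_dev <- n_dev + (p < cfg$hwe_alpha)
  }
  n_dev >= cfg$hwe_min_sites
}

#' Restrict to SNPs usable in redundancy-analysis scans
#'
#' Keeps SNPs that are polymorphic (both alleles observed among called
#' genotypes) in at least `cfg$min_variable_sites_rda` sites, removing
#' low-frequency markers that would destabilise constrained ordination.
#'
#' @inheritParams apply_filter_cascade
#' @return a filtered [geno_matrix()].
#' @export
select_rda_loci <- function(gm, cfg = filter_config()) {
  counts <- site_geno_counts(gm)
  # polymorphic within a site: alt count strictly between 0 and 2n
  poly <- counts$alt > 0 & counts$alt < 2 * counts$n
  keep <- colSums(poly) >= cfg$min_variable_sites_rda
  assert_that(any(keep), "no SNPs variable in enough sites")
  drop_snps(gm, keep)
}
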