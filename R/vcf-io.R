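#' Read a VCF into a genotype matrix
#'
#' Loads diploid biallelic SNP records from a VCFv4.x file (via
#' \pkg{vcfR}), encoding genotypes as alternate-allele counts. Multi-allelic
#' records are excluded and counted. Locus structure for RADseq-style data is
#' taken from the CHROM column (one RAD locus per chromosome entry) and the
#' POS column gives the position within the locus.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sites optional site registry tibble (`site_id`, `x`, `y`, ...). When
#'   supplied, individuals are mapped to sites via a `site_id` column matched
#'   on `ind_id`; otherwise all samples are placed in one site.
#' @param ind_sites optional tibble (`ind_id`, `site_id`) assigning samples to
#'   sites.
#' @return a [geno_matrix()]; the number of excluded multi-allelic records is
#'   attached as attribute `n_multiallelic`.
#' @export
read_vcf <- function(path, sites = NULL, ind_sites = NULL) {
  assert_that(file.exists(path), paste0("no such VCF: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  assert_that(ncol(vcf@gt) >= 2, "VCF contains no sample columns")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    message(sprintf("read_vcf: excluded %d multi-allelic record(s)", n_multi))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  assert_that(nrow(fix) > 0, "VCF holds no biallelic records")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  clean <- gsub("|", "/", gt, fixed = TRUE)
  g_t <- matrix(NA_integer_, nrow(gt), ncol(gt))
  g_t[clean == "0/0"] <- 0L
  g_t[clean %in% c("0/1", "1/0")] <- 1L
  g_t[clean == "1/1"] <- 2L
  unknown <- !is.na(clean) & !(clean %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown)) {
    rec <- (which(unknown)[1] - 1L) %% nrow(gt) + 1L
    stop(sprintf("read_vcf: unparseable genotype '%s' at record %s:%s",
                 clean[which(unknown)[1]], fix[rec, "CHROM"], fix[rec, "POS"]),
         call. = FALSE)
  }

  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  mean_depth <- if (!is.null(dp)) rowMeans(dp, na.rm = TRUE) else NA_real_
  mean_depth[is.nan(mean_depth)] <- NA_real_

  snp_id <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  if (anyDuplicated(snp_id)) snp_id <- make.unique(snp_id, sep = "_dup")
  snp_meta <- tibble(
    snp_id = snp_id,
    locus_id = fix[, "CHROM"],
    pos_in_locus = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    mean_depth = as.numeric(mean_depth)
  )
  geno <- t(g_t)
  rownames(geno) <- colnames(gt)
  colnames(geno) <- snp_id

  im <- if (!is.null(ind_sites)) {
    as_tibble(ind_sites)[match(rownames(geno), ind_sites$ind_id), ]
  } else {
    tibble(ind_id = rownames(geno), site_id = "site1")
  }
  gm <- geno_matrix(geno, snp_meta = snp_meta, ind_meta = im, sites = sites)
  attr(gm, "n_multiallelic") <- n_multi
  gm
}

#' Write a genotype matrix as VCFv4.2
#'
#' Emits a minimal plain-text VCF with GT and (when depths are simulated or
#' recorded) DP fields, suitable for interchange with standard tooling.
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @param depths optional individuals x SNPs integer matrix of per-genotype
#'   read depths.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, depths = NULL) {
  g <- gm$genotypes
  sm <- gm$snp_meta
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=frogcu",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(depths))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t")
  )
  fmt <- if (is.null(depths)) "GT" else "GT:DP"
  body <- vapply(seq_len(ncol(g)), function(j) {
    calls <- ifelse(is.na(g[, j]), "./.", gt_code[as.character(g[, j])])
    if (!is.null(depths)) {
      calls <- paste0(calls, ":", ifelse(is.na(g[, j]), ".", depths[, j]))
    }
    paste(c(sm$locus_id[j], sm$pos_in_locus[j], sm$snp_id[j], sm$ref[j],
            sm$alt[j], ".", "PASS", ".", fmt, calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
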