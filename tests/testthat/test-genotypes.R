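test_that("VCF genotypes are decoded to alternate-allele counts", {
  path <- toy_vcf(c(
    vcf_header(c("A1", "A2")),
    "loc1\t10\tloc1_10\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:12\t1/1:20",
    "loc1\t40\tloc1_40\tG\tC\t.\tPASS\t.\tGT:DP\t./.:.\t0|0:9",
    "loc2\t5\tloc2_5\tA\tC,G\t.\tPASS\t.\tGT:DP\t0/1:10\t0/2:10"
  ))
  expect_message(gm <- read_vcf(path), "1 multi-allelic")
  expect_equal(dim(gm$genotypes), c(2, 2))
  expect_equal(unname(gm$genotypes[, "loc1_10"]), c(1L, 2L))
  expect_true(is.na(gm$genotypes["A1", "loc1_40"]))
  expect_equal(gm$genotypes[["A2", "loc1_40"]], 0L)
  expect_equal(attr(gm, "n_multiallelic"), 1L)
  expect_equal(gm$snp_meta$pos_in_locus, c(10L, 40L))
  expect_equal(gm$snp_meta$mean_depth[1], 16)
})

test_that("VCF round trip preserves genotypes and metadata", {
  gm <- random_gm(2, 5, 12, seed = 42, missing_rate = 0.1)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, ind_sites = gm$ind_meta)
  expect_equal(unname(back$genotypes), unname(gm$genotypes))
  expect_equal(back$ind_meta$site_id, gm$ind_meta$site_id)
})

test_that("reading a VCF with no samples fails", {
  path <- toy_vcf(c("##fileformat=VCFv4.2",
                    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO"), collapse = "\t"),
                    "loc1\t10\t.\tA\tT\t.\tPASS\t."))
  expect_error(suppressWarnings(read_vcf(path)))
})

test_that("MAC boundary: count 9 is removed, count 10 retained", {
  # 30 individuals, one site; SNP1 has exactly 9 alt alleles, SNP2 has 10
  g <- matrix(0L, 30, 2)
  g[1:4, 1] <- 2L; g[5, 1] <- 1L            # MAC 9
  g[1:5, 2] <- 2L                           # MAC 10
  gm <- toy_gm(g)
  res <- apply_filter_cascade(gm, filter_config(hwe_min_sites = 99))
  expect_identical(colnames(res$gm$genotypes), "s2")
  step <- res$report[res$report$step == "global_mac", ]
  expect_equal(step$snps_removed, 1L)
})

test_that("individuals beyond the missingness ceiling are dropped", {
  g <- matrix(1L, 10, 20)
  g[1, 1:12] <- NA_integer_   # 60% missing
  g[2, 1:11] <- NA_integer_   # 55% missing: kept (rule is strictly greater)
  gm <- toy_gm(g)
  res <- apply_filter_cascade(
    gm, filter_config(min_global_mac = 1, min_locus_call_rate = 0.5,
                      hwe_min_sites = 99, allhet_site_min_n = 99))
  expect_equal(res$report$inds_removed[1], 1L)
  expect_false("i1" %in% rownames(res$gm$genotypes))
  expect_true("i2" %in% rownames(res$gm$genotypes))
})

test_that("an all-heterozygote SNP at a well-genotyped site is removed", {
  g <- cbind(rep(1L, 7), c(0L, 1L, 2L, 0L, 1L, 2L, 0L))
  gm <- toy_gm(g)
  res <- apply_filter_cascade(gm, filter_config(min_global_mac = 1,
                                                hwe_min_sites = 99))
  expect_identical(colnames(res$gm$genotypes), "s2")
  # with only 6 genotyped individuals the screen does not apply
  g2 <- g; g2[7, 1] <- NA_integer_
  res2 <- apply_filter_cascade(
    toy_gm(g2), filter_config(min_global_mac = 1, hwe_min_sites = 99,
                              min_locus_call_rate = 0.5))
  expect_true("s1" %in% colnames(res2$gm$genotypes))
})

test_that("loci with too many SNPs are removed whole; densest SNP kept otherwise", {
  set.seed(1)
  n <- 20
  g <- matrix(rbinom(n * 10, 2, 0.5), n, 10)
  snp_meta <- tibble::tibble(
    snp_id = paste0("s", 1:10),
    locus_id = c(rep("locA", 8), "locB", "locB"),
    pos_in_locus = c(1:8, 1L, 2L),
    ref = "A", alt = "T", mean_depth = 30
  )
  colnames(g) <- snp_meta$snp_id
  gm <- toy_gm(g, snp_meta = snp_meta)
  res <- apply_filter_cascade(gm, filter_config(min_global_mac = 1,
                                                hwe_min_sites = 99,
                                                allhet_site_min_n = 99))
  # locA carried 8 SNPs -> removed whole; locB reduced to its best SNP
  expect_false(any(grepl("^s[1-8]$", colnames(res$gm$genotypes))))
  kept <- res$gm$snp_meta
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$locus_id, "locB")
  macs <- global_mac(gm)
  want <- if (macs["s9"] >= macs["s10"]) "s9" else "s10"
  expect_equal(kept$snp_id, want)
})

test_that("ideal Hardy-Weinberg proportions pass the HWE screen", {
  # two sites of 100, each exactly 25/50/25 at both SNPs
  block <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  g <- cbind(rep(block, 2), rep(block, 2))
  gm <- toy_gm(g, sites_of_rows = rep(c("A", "B"), each = 100))
  res <- apply_filter_cascade(gm, filter_config(hwe_min_sites = 2))
  expect_equal(res$report$snps_removed[res$report$step == "hwe"], 0L)

  # an extreme heterozygote excess at both sites is caught
  g2 <- cbind(g[, 1], rep(1L, 200))
  g2[1, 2] <- 0L; g2[2, 2] <- 2L  # not all-het, still wildly out of HWE
  res2 <- apply_filter_cascade(toy_gm(g2, rep(c("A", "B"), each = 100)),
                               filter_config(hwe_min_sites = 2))
  expect_equal(res2$report$snps_removed[res2$report$step == "hwe"], 1L)
})

test_that("the cascade is idempotent and its report reconciles", {
  gm <- random_gm(4, 12, 150, seed = 11, missing_rate = 0.08)
  cfg <- filter_config(min_global_mac = 3)
  res <- apply_filter_cascade(gm, cfg)
  rep1 <- res$report
  expect_true(all(diff(rep1$snps_left) <= 0))
  expect_true(all(rep1$snps_left + cumsum(rep1$snps_removed) == 150))
  res2 <- apply_filter_cascade(res$gm, cfg)
  expect_equal(sum(res2$report$snps_removed), 0L)
  expect_equal(sum(res2$report$inds_removed), 0L)
  expect_identical(res2$gm$genotypes, res$gm$genotypes)
})

test_that("empty output after a step is an error naming the step", {
  g <- matrix(c(0L, 0L, 0L, 2L), 4, 1)  # MAC 2 < 10
  expect_error(apply_filter_cascade(toy_gm(g)), "global_mac")
})

test_that("rda locus selection applies the variable-sites rule at its boundary", {
  # SNP variable in 2 sites -> removed; in 3 sites -> retained;
  # monomorphic everywhere -> removed
  sites <- rep(c("A", "B", "C", "D"), each = 4)
  v2 <- c(rep(c(0L, 1L), 4), rep(0L, 8))       # variable in sites A, B
  v3 <- c(rep(c(0L, 1L), 6), rep(0L, 4))       # variable in A, B, C
  mono <- rep(1L, 16)                          # het everywhere, still variable?
  fixed <- rep(2L, 16)                         # monomorphic
  gm <- toy_gm(cbind(v2, v3, fixed), sites_of_rows = sites)
  out <- select_rda_loci(gm, filter_config(min_variable_sites_rda = 3))
  expect_identical(colnames(out$genotypes), "v3")
})

test_that("hwe exact test agrees with direct enumeration", {
  set.seed(99)
  for (trial in 1:60) {
    n <- sample(2:20, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
    p_pkg <- hwe_exact_test(counts[1], counts[2], counts[3])
    p_ora <- oracle_hwe_exact(counts[1], counts[2], counts[3])
    expect_equal(p_pkg, p_ora, tolerance = 1e-10)
  }
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 0.05)
})
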