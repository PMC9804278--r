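test_that("mode imputation fills gaps deterministically", {
  g <- matrix(c(0L, 0L, 1L, NA,
                2L, 2L, NA, 2L,
                0L, 2L, NA, NA), 4, 3)
  gm <- toy_gm(g)
  imp <- impute_missing_mode(gm)
  expect_false(anyNA(imp))
  expect_equal(imp[4, 1], 0L)          # site mode of {0,0,1}
  expect_equal(imp[3, 2], 2L)
  expect_equal(imp[3, 3], 0L)          # tie between 0 and 2 -> lower code
  expect_equal(imp[4, 3], 0L)

  # no missing input -> identity
  g2 <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  expect_identical(impute_missing_mode(toy_gm(g2)), toy_gm(g2)$genotypes)

  # site-wide missing SNP falls back to the global mode
  g3 <- rbind(matrix(c(2L, 2L, NA, NA), 2, 2),
              matrix(c(NA, NA, 0L, 0L), 2, 2))
  gm3 <- toy_gm(g3, sites_of_rows = c("A", "A", "B", "B"))
  imp3 <- impute_missing_mode(gm3)
  expect_equal(unname(imp3[3:4, 1]), c(2L, 2L))
  expect_equal(unname(imp3[1:2, 2]), c(0L, 0L))

  g4 <- matrix(c(1L, NA, NA, NA), 2, 2)
  expect_error(impute_missing_mode(toy_gm(g4)), "zero calls")
})

test_that("rda eigenvalues and loadings agree with a direct SVD evaluation", {
  set.seed(44)
  Y <- matrix(rnorm(20 * 15), 20, 15)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  Z <- data.frame(z1 = rnorm(20))
  m <- fit_rda(Y, X)
  expect_equal(m$eigenvalues, oracle_rda_eig(Y, X), tolerance = 1e-8)
  m2 <- fit_rda(Y, X, conditioners = Z)
  expect_equal(m2$eigenvalues, oracle_rda_eig(Y, X, Z), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_lte(length(m$eigenvalues), ncol(X))
})

test_that("conditioning on the predictors annihilates the constrained signal", {
  set.seed(4)
  Y <- matrix(rnorm(15 * 8), 15, 8)
  X <- data.frame(a = rnorm(15), b = rnorm(15))
  m <- fit_rda(Y, X, conditioners = X)
  expect_equal(sum(m$eigenvalues), 0, tolerance = 1e-10)
})

test_that("a SNP identical to the predictor attains the maximal loading", {
  set.seed(10)
  x <- rnorm(20)
  Y <- cbind(matrix(rnorm(20 * 30, sd = 1), 20, 30), signal = x)
  colnames(Y) <- c(paste0("n", 1:30), "signal")
  m <- fit_rda(Y, data.frame(x = x))
  l1 <- abs(m$loadings[, 1])
  expect_equal(names(which.max(l1)), "signal")
})

test_that("rda input validation catches degenerate designs", {
  Y <- matrix(rnorm(30), 10, 3)
  expect_error(fit_rda(Y, data.frame(a = rep(1, 10))), "zero-variance")
  x <- rnorm(10)
  expect_error(fit_rda(Y, data.frame(a = x, b = 2 * x)), "collinear")
  expect_error(fit_rda(Y, data.frame(a = rnorm(3))), "align")
})

test_that("outlier detection flags the planted loci and few neutrals", {
  cfg <- sim_config(seed = 19, n_sites = 31, n_ind_per_site = 12,
                    n_neutral = 1200, n_adaptive = 30,
                    landscape_extent = 20000)
  sim <- simulate_genotypes(cfg)
  freq <- site_allele_freq(sim$gm)
  freq[is.na(freq)] <- 0.5
  pred <- as.data.frame(sim$env[match(rownames(freq), sim$env$site_id),
                                c("summer_precip", "fprecip", "winter_tmin")])
  m <- fit_rda(freq, pred)
  cand <- detect_outliers_sd(m, freq, pred, n_axes = 2, threshold_sd = 3.5)
  truth <- sim$truth$adaptive_locus_ids
  power <- mean(truth %in% cand$snp_id)
  fpr <- mean(setdiff(colnames(freq), truth) %in% cand$snp_id)
  expect_gte(power, 0.6)
  expect_lte(fpr, 0.01)
  # assignment picks the most correlated predictor
  expect_true(all(cand$predictor %in% names(pred)))
})

test_that("outlier detection honours degenerate loadings and sign flips", {
  set.seed(2)
  Y <- matrix(rnorm(20 * 50), 20, 50)
  colnames(Y) <- paste0("s", 1:50)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  m <- fit_rda(Y, X)
  cand <- detect_outliers_sd(m, Y, X, n_axes = 2, threshold_sd = 2.0)
  m_flip <- m
  m_flip$loadings <- -m$loadings
  cand_flip <- detect_outliers_sd(m_flip, Y, X, n_axes = 2,
                                  threshold_sd = 2.0)
  expect_setequal(cand$snp_id, cand_flip$snp_id)

  m0 <- m
  m0$loadings[, 1:2] <- 1
  expect_warning(none <- detect_outliers_sd(m0, Y, X), "zero loading")
  expect_equal(nrow(none), 0L)
})

test_that("the flagged fraction under the null tracks the normal tail", {
  set.seed(55)
  n_snps <- 40000
  Y <- matrix(rnorm(30 * n_snps), 30, n_snps)
  colnames(Y) <- paste0("s", seq_len(n_snps))
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  m <- fit_rda(Y, X)
  z <- scale(m$loadings[, 1:2])
  frac <- colMeans(abs(z) >= 3.5)
  expected <- 2 * pnorm(-3.5)
  for (f in frac) {
    expect_gt(f, expected * 0.5)
    expect_lt(f, expected * 2.0)
  }
})

test_that("batch-effect removal strips the planted lane signal", {
  set.seed(30)
  n <- 60; L <- 10000; shifted <- 100
  g <- matrix(rbinom(n * L, 2, 0.5), n, L)
  colnames(g) <- paste0("s", 1:L)
  batch <- rep(c("lane1", "lane2"), each = n / 2)
  # lane effect: first 100 SNPs get an allele-frequency shift in lane 2
  idx <- batch == "lane2"
  g[idx, 1:shifted] <- rbinom(sum(idx) * shifted, 2, 0.95)
  out <- remove_batch_effect(g, batch, threshold_sd = 4)
  recovered <- mean(paste0("s", 1:shifted) %in% out$removed)
  expect_gte(recovered, 0.8)

  # without a batch effect removals stay near the normal-tail expectation
  g0 <- matrix(rbinom(n * L, 2, 0.5), n, L)
  colnames(g0) <- paste0("s", 1:L)
  out0 <- remove_batch_effect(g0, batch, threshold_sd = 4)
  expect_lte(length(out0$removed), max(4, 2 * 2 * pnorm(-4) * L))

  expect_error(remove_batch_effect(g, rep("lane1", n)), "2 batches")
})

test_that("genotype pca behaves on constructed inputs", {
  set.seed(3)
  base <- matrix(rbinom(40, 2, 0.5), 4, 10)
  dup <- base[c(1, 1, 2, 3, 4), ]
  p <- pca_genotypes(dup, n_axes = 2)
  expect_equal(unlist(p$scores[1, -1]), unlist(p$scores[2, -1]),
               tolerance = 1e-10)

  # two separated clusters: PC1 gap exceeds within-cluster spread
  g1 <- matrix(rbinom(10 * 50, 2, 0.15), 10, 50)
  g2 <- matrix(rbinom(10 * 50, 2, 0.85), 10, 50)
  p2 <- pca_genotypes(rbind(g1, g2), n_axes = 2)
  pc1 <- p2$scores$PC1
  gap <- abs(mean(pc1[1:10]) - mean(pc1[11:20]))
  spread <- max(sd(pc1[1:10]), sd(pc1[11:20]))
  expect_gt(gap, 3 * spread)

  expect_warning(pca_genotypes(base[1:3, ], n_axes = 10), "truncated")
})
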