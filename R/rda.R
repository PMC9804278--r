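#' Check a predictor table for collinearity
#'
#' @param predictors data frame of numeric predictors (one row per site or
#'   individual).
#' @param threshold maximum tolerated absolute pairwise Pearson correlation.
#' @return invisibly `TRUE`; errors naming the first offending pair.
#' @export
check_predictor_correlation <- function(predictors, threshold = 0.6) {
  p <- as.data.frame(predictors)
  nm <- names(p)
  if (ncol(p) < 2) return(invisible(TRUE))
  r <- cor(p)
  idx <- pair_index(ncol(p))
  bad <- which(abs(r[idx]) >= threshold)
  if (length(bad) > 0) {
    k <- bad[1]
    stop(sprintf("predictors '%s' and '%s' are correlated (|r| = %.2f >= %.2f)",
                 nm[idx[k, 1]], nm[idx[k, 2]], abs(r[idx])[k], threshold),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Redundancy analysis, optionally partial
#'
#' Constrained ordination of a response matrix (genotypes or site allele
#' frequencies) on environmental predictors, with optional conditioning
#' variables whose effect is removed from both response and predictors
#' before the constrained decomposition (partial RDA). A thin wrapper
#' around [vegan::rda()] that standardises the pieces downstream code
#' needs: constrained eigenvalues, row scores and per-SNP loadings.
#'
#' @param response numeric matrix / data frame, rows aligned with
#'   `predictors` (and `conditioners`). Columns are centred by the
#'   underlying ordination; they are not variance-scaled.
#' @param predictors data frame of constraining variables.
#' @param conditioners optional data frame of conditioning variables.
#' @return an `rda_model`: `eigenvalues`, `site_scores`, `loadings`
#'   (SNPs x axes), `predictor_names`, `n_conditioners`, `n`, and the
#'   underlying vegan object in `fit`.
#' @export
fit_rda <- function(response, predictors, conditioners = NULL) {
  Y <- as.matrix(response)
  X <- as.data.frame(predictors)
  assert_that(nrow(Y) == nrow(X), "response and predictors must align")
  n_cond <- 0L
  if (!is.null(conditioners)) {
    Z <- as.data.frame(conditioners)
    assert_that(nrow(Z) == nrow(Y), "conditioners must align with response")
    n_cond <- ncol(Z)
  }
  assert_that(nrow(Y) > ncol(X) + n_cond,
              "need more rows than predictors plus conditioners")
  sds <- vapply(X, sd, numeric(1))
  if (any(sds == 0)) {
    stop(sprintf("zero-variance predictor: %s",
                 paste(names(X)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  if (ncol(X) >= 2) {
    r <- cor(X)
    idx <- pair_index(ncol(X))
    bad <- which(abs(r[idx]) > 0.9999)
    if (length(bad) > 0) {
      stop(sprintf("predictors '%s' and '%s' are collinear",
                   names(X)[idx[bad[1], 1]], names(X)[idx[bad[1], 2]]),
           call. = FALSE)
    }
  }
  fit <- if (n_cond > 0) {
    vegan::rda(X = Y, Y = X, Z = as.data.frame(conditioners))
  } else {
    vegan::rda(X = Y, Y = X)
  }
  eig <- fit$CCA$eig %||% numeric(0)
  loadings <- fit$CCA$v
  scores <- fit$CCA$u
  structure(list(
    eigenvalues = as.numeric(eig),
    site_scores = scores,
    loadings = loadings,
    predictor_names = names(X),
    n_conditioners = n_cond,
    n = nrow(Y),
    n_snps = ncol(Y),
    residual_rank = fit$CA$rank %||% 0L,
    fit = fit
  ), class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("<rda_model> %d rows x %d SNPs, %d constrained axes%s\n",
              x$n, x$n_snps, length(x$eigenvalues),
              if (x$n_conditioners > 0)
                sprintf(" (partial, %d conditioners)", x$n_conditioners)
              else ""))
  invisible(x)
}

#' Tidy SNP loadings of an RDA model
#' @param x an `rda_model`.
#' @param ... unused.
#' @return tibble `snp_id`, `axis`, `loading`.
#' @method tidy rda_model
#' @export
tidy.rda_model <- function(x, ...) {
  l <- x$loadings
  tibble(
    snp_id = rep(rownames(l), ncol(l)),
    axis = rep(seq_len(ncol(l)), each = nrow(l)),
    loading = as.vector(l)
  )
}

#' @method glance rda_model
#' @export
glance.rda_model <- function(x, ...) {
  tibble(
    n = x$n, n_snps = x$n_snps,
    n_constrained_axes = length(x$eigenvalues),
    constrained_inertia = sum(x$eigenvalues),
    n_conditioners = x$n_conditioners
  )
}

#' Principal component analysis of an imputed genotype table
#'
#' Column-centred PCA (no variance scaling), returning scores for the
#' leading axes together with eigenvalues and percent variance.
#'
#' @param geno complete individuals x SNPs numeric matrix.
#' @param n_axes number of axes to return (truncated to the matrix rank
#'   with a warning when too large).
#' @return a list: `scores` tibble (row ids + `PC1..PCk`), `eigenvalues`,
#'   `pct_var`.
#' @export
pca_genotypes <- function(geno, n_axes = 2L) {
  g <- as.matrix(geno)
  assert_that(nrow(g) >= 2, "need at least two rows")
  pc <- prcomp(g, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (n_axes > rank) {
    warning(sprintf("n_axes truncated from %d to rank %d", n_axes, rank))
    n_axes <- rank
  }
  eig <- pc$sdev^2
  scores <- as_tibble(pc$x[, seq_len(n_axes), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(row_id = rownames(g) %||%
                                      as.character(seq_len(nrow(g)))), scores)
  list(scores = scores, eigenvalues = eig[seq_len(n_axes)],
       pct_var = 100 * eig[seq_len(n_axes)] / sum(eig))
}
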