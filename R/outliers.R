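#' Detect candidate adaptive SNPs by loading outliers
#'
#' Standardises the SNP loadings of each of the first `n_axes` constrained
#' axes and flags SNPs whose loading sits at least `threshold_sd` standard
#' deviations from the mean loading on any of those axes (each SNP flagged
#' once, on the axis where its |z| is largest). Each candidate is assigned
#' the predictor with the strongest absolute Pearson correlation to its
#' response column.
#'
#' @param model an [fit_rda()] result.
#' @param response the response matrix the model was fitted to (used for
#'   candidate-predictor correlations).
#' @param predictors the predictor data frame used in the fit.
#' @param n_axes number of leading constrained axes to scan.
#' @param threshold_sd outlier threshold in SD units.
#' @return a `candidate_set` tibble: `snp_id`, `axis`, `loading`, `z`,
#'   `predictor`, `r`; empty (with a warning) when loadings have zero
#'   spread. The threshold is attached as attribute `threshold_sd`.
#' @export
detect_outliers_sd <- function(model, response, predictors, n_axes = 2L,
                               threshold_sd = 3.5) {
  assert_that(inherits(model, "rda_model"), "model must be an rda_model")
  l <- model$loadings
  assert_that(!is.null(l) && ncol(l) >= n_axes,
              sprintf("model has fewer than %d constrained axes", n_axes))
  l <- l[, seq_len(n_axes), drop = FALSE]
  sds <- apply(l, 2, sd)
  if (any(sds == 0)) {
    warning("zero loading spread on a constrained axis: no candidates")
    out <- tibble(snp_id = character(0), axis = integer(0),
                  loading = numeric(0), z = numeric(0),
                  predictor = character(0), r = numeric(0))
    attr(out, "threshold_sd") <- threshold_sd
    class(out) <- c("candidate_set", class(out))
    return(out)
  }
  z <- scale(l)
  hit <- abs(z) >= threshold_sd
  flagged <- which(rowSums(hit) > 0)
  best_axis <- apply(abs(z[flagged, , drop = FALSE]), 1, which.max)

  X <- as.data.frame(predictors)
  resp <- as.matrix(response)
  pred_name <- character(length(flagged))
  pred_r <- numeric(length(flagged))
  for (k in seq_along(flagged)) {
    rs <- vapply(X, function(xx) {
      suppressWarnings(cor(resp[, flagged[k]], xx))
    }, numeric(1))
    rs[is.na(rs)] <- 0
    pred_name[k] <- names(X)[which.max(abs(rs))]
    pred_r[k] <- rs[which.max(abs(rs))]
  }
  out <- tibble(
    snp_id = rownames(l)[flagged],
    axis = as.integer(best_axis),
    loading = l[cbind(flagged, best_axis)],
    z = z[cbind(flagged, best_axis)],
    predictor = pred_name,
    r = pred_r
  )
  attr(out, "threshold_sd") <- threshold_sd
  class(out) <- c("candidate_set", class(out))
  out
}

#' Remove SNPs carrying a batch (library/lane) effect
#'
#' Fits an RDA of the complete genotype table on batch indicator(s) and
#' removes SNPs whose loading on the first constrained axis lies at least
#' `threshold_sd` SDs from the mean -- the markers that encode the
#' technical batch signal rather than biology.
#'
#' @param geno complete individuals x SNPs numeric matrix.
#' @param batch factor-like vector of batch labels, one per row.
#' @param threshold_sd outlier threshold in SD units.
#' @return list with `geno` (reduced matrix) and `removed` (SNP ids).
#' @export
remove_batch_effect <- function(geno, batch, threshold_sd = 4) {
  g <- as.matrix(geno)
  batch <- as.factor(batch)
  assert_that(nlevels(droplevels(batch)) >= 2,
              "batch-effect removal needs at least 2 batches")
  X <- as.data.frame(stats::model.matrix(~batch)[, -1, drop = FALSE])
  model <- fit_rda(g, X)
  z <- scale(model$loadings[, 1, drop = FALSE])
  drop <- abs(z[, 1]) >= threshold_sd
  list(geno = g[, !drop, drop = FALSE],
       removed = colnames(g)[drop])
}
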