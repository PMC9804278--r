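#' Hierarchical AMOVA over a candidate site grouping
#'
#' Three-level analysis of molecular variance (among groups / among sites
#' within groups / within sites) on squared Euclidean distances between
#' individual genotype vectors. Markers are pruned to low missingness and
#' remaining gaps are mean-imputed per SNP, so the decomposition is exact
#' and deterministic. Variance components use the standard nested
#' unequal-sample-size coefficients; negative components are reported and
#' flagged rather than truncated.
#'
#' @param gm a [geno_matrix()].
#' @param grouping tibble `site_id`, `group` covering every site; at least
#'   two groups.
#' @param max_missing markers with a missing fraction at or above this are
#'   dropped before the decomposition.
#' @param name label stored on the result.
#' @return an `amova_result` tibble with rows `among_groups`,
#'   `among_sites`, `within_sites`: `df`, `ss`, `ms`, `variance`, `pct`;
#'   attributes `grouping`, `n_groups`, `degenerate`,
#'   `negative_components`.
#' @export
run_amova <- function(gm, grouping, max_missing = 0.05, name = "grouping") {
  grouping <- as_tibble(grouping)
  assert_that(all(c("site_id", "group") %in% names(grouping)),
              "grouping needs columns site_id and group")
  sites_present <- unique(site_of(gm))
  assert_that(all(sites_present %in% grouping$site_id),
              "grouping must cover every site")
  grp_of_site <- setNames(as.character(grouping$group), grouping$site_id)
  assert_that(length(unique(grp_of_site[sites_present])) >= 2,
              "grouping must define at least two groups")

  miss <- colMeans(is.na(gm$genotypes))
  keep <- miss < max_missing
  assert_that(any(keep), "no markers pass the missingness prune")
  X <- gm$genotypes[, keep, drop = FALSE]
  storage.mode(X) <- "double"
  # mean-impute per SNP
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }

  site <- site_of(gm)
  grp <- grp_of_site[site]
  N <- nrow(X)
  site_f <- factor(site)
  grp_f <- factor(grp)
  S <- nlevels(site_f)
  G <- nlevels(grp_f)

  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2, grand)^2)

  site_means <- rowsum(X, site_f) / as.vector(table(site_f))
  n_s <- as.vector(table(site_f))
  grp_of_site_lvl <- grp_f[match(levels(site_f), site_f)]
  grp_means <- rowsum(X, grp_f) / as.vector(table(grp_f))
  N_g <- as.vector(table(grp_f))

  ss_within <- sum((X - site_means[as.integer(site_f), , drop = FALSE])^2)
  ss_among_groups <- sum(N_g * rowSums(sweep(grp_means, 2, grand)^2))
  ss_among_sites <- sum(n_s * rowSums(
    (site_means - grp_means[as.integer(grp_of_site_lvl), , drop = FALSE])^2))

  df_ag <- G - 1
  df_as <- S - G
  df_ws <- N - S
  degenerate <- ss_total < 1e-12

  ms_ws <- if (df_ws > 0) ss_within / df_ws else 0
  ms_as <- if (df_as > 0) ss_among_sites / df_as else NA_real_
  ms_ag <- ss_among_groups / df_ag

  # unequal-size coefficients of the nested random-effects model
  n_in_g <- tapply(n_s, grp_of_site_lvl, sum)
  sum_ns2_by_g <- tapply(n_s^2, grp_of_site_lvl, sum)
  n1 <- if (df_as > 0) (N - sum(sum_ns2_by_g / n_in_g)) / df_as else NA_real_
  n2 <- (sum(sum_ns2_by_g / n_in_g) - sum(n_s^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag

  sigma_c <- ms_ws
  sigma_b <- if (df_as > 0 && is.finite(n1) && n1 > 0)
    (ms_as - sigma_c) / n1 else 0
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  comps <- c(among_groups = sigma_a, among_sites = sigma_b,
             within_sites = sigma_c)
  total <- sum(comps)
  pct <- if (degenerate || total == 0) rep(NA_real_, 3) else
    100 * comps / total

  out <- tibble(
    stratum = names(comps),
    df = c(df_ag, df_as, df_ws),
    ss = c(ss_among_groups, ss_among_sites, ss_within),
    ms = c(ms_ag, ms_as, ms_ws),
    variance = as.numeric(comps),
    pct = as.numeric(pct)
  )
  attr(out, "grouping") <- name
  attr(out, "n_groups") <- G
  attr(out, "degenerate") <- degenerate
  attr(out, "negative_components") <- any(comps < 0)
  attr(out, "ss_total") <- ss_total
  class(out) <- c("amova_result", class(out))
  out
}

#' Compare candidate management-unit groupings by AMOVA
#'
#' Runs [run_amova()] for each grouping and ranks by the among-group
#' percentage of variance, the criterion used to judge how well a
#' delineation captures genetic structure. The number of groups is
#' reported alongside, since a grouping with many singleton sites can win
#' on percentage while being useless for management.
#'
#' @param gm a [geno_matrix()].
#' @param groupings named list of grouping tibbles (`site_id`, `group`).
#' @param max_missing passed to [run_amova()].
#' @return a tibble ranked by `pct_among_groups` (descending), with the
#'   full results in attribute `results`.
#' @export
compare_groupings <- function(gm, groupings, max_missing = 0.05) {
  assert_that(length(groupings) >= 2, "need at least two groupings")
  nms <- names(groupings) %||% paste0("grouping", seq_along(groupings))
  assert_that(!anyDuplicated(nms), "duplicate grouping names")
  res <- lapply(seq_along(groupings), function(i)
    run_amova(gm, groupings[[i]], max_missing = max_missing, name = nms[i]))
  tab <- dplyr::bind_rows(lapply(res, function(r) tibble(
    grouping = attr(r, "grouping"),
    n_groups = attr(r, "n_groups"),
    pct_among_groups = r$pct[r$stratum == "among_groups"],
    pct_among_sites = r$pct[r$stratum == "among_sites"],
    pct_within_sites = r$pct[r$stratum == "within_sites"]
  )))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$pct_among_groups))
  attr(tab, "results") <- setNames(res, nms)
  tab
}
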