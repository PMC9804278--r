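#' Published reference tables for the Nevada spotted frog populations
#'
#' Small plain-text tables of published site-level results for the Great
#' Basin Columbia spotted frog populations of Nevada, bundled for
#' cross-checking pipeline output formats and for arithmetic summaries:
#'
#' * `nevada_ne_table()`: corrected LD-Ne point estimates (Pcrit = 0.05,
#'   corrected for 13 chromosome pairs) with jackknife CIs for the 28 sites
#'   with adequate sample sizes; `"inf"` upper bounds are parsed to `Inf`.
#' * `nevada_diversity_table()`: observed/expected heterozygosity,
#'   nucleotide diversity and private allele counts for all 31 sites.
#' * `nevada_gravity_models()`: the 11-hypothesis connectivity competition
#'   (AICc, BIC, log-likelihood, delta AICc; the global model did not
#'   converge).
#' * `nevada_gravity_coefficients()`: standardised coefficients of the
#'   best-supported temperature-moisture model.
#' * `nevada_candidate_counts()`: counts of candidate adaptive SNPs by
#'   most-correlated environmental predictor.
#' * `nevada_amova_table()`: AMOVA percent-variance rows for the candidate
#'   management-unit delineations.
#'
#' @return a tibble.
#' @name nevada_tables
NULL

read_pkg_table <- function(file) {
  path <- system.file("extdata", file, package = "frogcu", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname nevada_tables
#' @export
nevada_ne_table <- function() {
  tab <- read_pkg_table("nevada_ne_table.csv")
  tab$ci_hi <- as.numeric(ifelse(tab$ci_hi == "inf", Inf, tab$ci_hi))
  tab
}

#' @rdname nevada_tables
#' @export
nevada_diversity_table <- function() read_pkg_table("nevada_diversity_table.csv")

#' @rdname nevada_tables
#' @export
nevada_gravity_models <- function() read_pkg_table("nevada_gravity_models.csv")

#' @rdname nevada_tables
#' @export
nevada_gravity_coefficients <- function()
  read_pkg_table("nevada_gravity_coefficients.csv")

#' @rdname nevada_tables
#' @export
nevada_candidate_counts <- function() read_pkg_table("nevada_candidate_counts.csv")

#' @rdname nevada_tables
#' @export
nevada_amova_table <- function() read_pkg_table("nevada_amova_table.csv")
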