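#' Configuration of a full pipeline run
#'
#' Either real inputs (VCF + site table + environment table) or a
#' [sim_config()] must be supplied, not neither. When a simulation config
#' is given, the rasters, flows and truth travel with the run.
#'
#' @param synth a [sim_config()], or `NULL` when reading files.
#' @param vcf,sites_csv,env_csv input file paths (used when `synth` is
#'   `NULL`).
#' @param filter a [filter_config()].
#' @param ne a [ne_config()].
#' @param n_condition_pcs conditioning PCs for the partial RDA scan.
#' @param outlier_sd candidate threshold in SD units.
#' @param hypotheses gravity hypothesis list.
#' @param groupings named list of grouping tibbles for AMOVA (optional;
#'   synthetic runs add the true grouping and the management-unit labels).
#' @param prune_km gravity graph pruning distance (km).
#' @param predict_max_km maximum distance for the pruned flow prediction.
#' @param flow_cutoff connectivity cutoff on the flow scale.
#' @param ne_min_n minimum site sample size for Ne estimation.
#' @param assayed_bp_per_locus assayed bases per RAD locus for nucleotide
#'   diversity.
#' @param seed master seed for any stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = NULL, vcf = NULL, sites_csv = NULL,
                       env_csv = NULL,
                       filter = filter_config(), ne = ne_config(),
                       n_condition_pcs = 7L, outlier_sd = 3.5,
                       hypotheses = default_hypotheses(),
                       groupings = NULL,
                       prune_km = 50, predict_max_km = 15,
                       flow_cutoff = 0.85, ne_min_n = 11L,
                       assayed_bp_per_locus = 90, seed = 1L) {
  if (is.null(synth) && is.null(vcf)) {
    stop("run_config needs either a sim_config or input files", call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full conservation-unit pipeline
#'
#' Executes the analysis stages in their canonical order: genotype
#' acquisition, filter cascade, genotype-environment outlier scan (the
#' candidate SNPs are then removed to form the neutral marker set), per-site
#' diversity, pairwise differentiation, LD-Ne, gravity-model competition
#' and flow prediction, and AMOVA comparison of site groupings. All tables
#' are written as CSVs under `out_dir`, plus a JSON manifest of per-stage
#' counts.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly a list with all in-memory results in
#'   attribute `results`.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("frogcu_run_")) {
  assert_that(inherits(cfg, "run_config"), "cfg must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  results <- list()
  stage <- function(name, value) {
    manifest$stages[[name]] <<- value
  }

  # -- stage 1: data -------------------------------------------------------
  if (!is.null(cfg$synth)) {
    sim <- simulate_genotypes(cfg$synth)
    gm <- sim$gm
    env <- sim$env
    rasters <- sim$rasters
    truth <- sim$truth
  } else {
    sites <- readr::read_csv(cfg$sites_csv, show_col_types = FALSE)
    ind_sites <- NULL
    gm <- read_vcf(cfg$vcf, sites = sites)
    env <- readr::read_csv(cfg$env_csv, show_col_types = FALSE)
    rasters <- NULL
    truth <- NULL
  }
  stage("data", list(n_ind = n_ind(gm), n_snp = n_snp(gm),
                     n_sites = nrow(gm$sites)))

  # -- stage 2: filter cascade --------------------------------------------
  filtered <- apply_filter_cascade(gm, cfg$filter)
  gm <- filtered$gm
  readr::write_csv(filtered$report, file.path(out_dir, "filter_report.csv"))
  stage("filter", list(n_snp = n_snp(gm), n_ind = n_ind(gm)))

  # -- stage 3: GEA candidate scan ----------------------------------------
  gm_rda <- select_rda_loci(gm, cfg$filter)
  freq <- site_allele_freq(gm_rda)
  site_order <- rownames(freq)
  pred <- as.data.frame(env[match(site_order, env$site_id),
                            setdiff(names(env), "site_id"), drop = FALSE])
  pred <- pred[, c("summer_precip", "fprecip", "winter_tmin")
               [c("summer_precip", "fprecip", "winter_tmin") %in% names(pred)],
               drop = FALSE]
  # frequencies are complete at site level except fully-missing cells
  freq[is.na(freq)] <- matrix(colMeans(freq, na.rm = TRUE),
                              nrow(freq), ncol(freq), byrow = TRUE)[is.na(freq)]
  cond <- NULL
  if (cfg$n_condition_pcs > 0) {
    pcs <- pca_genotypes(freq, n_axes = min(cfg$n_condition_pcs,
                                            nrow(freq) - ncol(pred) - 2L))
    cond <- as.data.frame(pcs$scores[, -1, drop = FALSE])
  }
  model <- fit_rda(freq, pred, conditioners = cond)
  candidates <- detect_outliers_sd(model, freq, pred,
                                   n_axes = min(2L, length(model$eigenvalues)),
                                   threshold_sd = cfg$outlier_sd)
  readr::write_csv(candidates, file.path(out_dir, "candidates.csv"))
  stage("gea", list(n_rda_snps = n_snp(gm_rda),
                    n_candidates = nrow(candidates)))

  # neutral set: candidates removed
  neutral <- gm_subset(gm, snps = setdiff(colnames(gm$genotypes),
                                          candidates$snp_id))
  stage("neutral_set", list(n_snp = n_snp(neutral)))

  # -- stage 4: diversity and differentiation -----------------------------
  div <- site_diversity(neutral,
                        assayed_length = cfg$assayed_bp_per_locus *
                          n_snp(neutral))
  readr::write_csv(div, file.path(out_dir, "diversity.csv"))
  fst <- pairwise_fst_wc(neutral)
  nei <- nei_distance_matrix(neutral)
  write.csv(fst$values, file.path(out_dir, "fst.csv"))
  write.csv(nei$values, file.path(out_dir, "nei_d.csv"))
  stage("popgen", list(n_sites = nrow(div),
                       mean_ho = mean(div$ho), mean_he = mean(div$he)))

  # -- stage 5: effective population size ---------------------------------
  ne_tab <- estimate_ne_all_sites(neutral, cfg$ne, min_n = cfg$ne_min_n)
  readr::write_csv(ne_tab, file.path(out_dir, "ne.csv"))
  stage("ne", list(n_estimates = nrow(ne_tab)))

  # -- stage 6: gravity models --------------------------------------------
  nodes <- dplyr::rename(gm$sites, id = "site_id")
  graph <- build_graph(nodes, method = "delaunay", prune_km = cfg$prune_km)
  if (!is.null(rasters)) {
    graph <- extract_edge_covariates(graph, rasters)
    graph$nodes <- extract_node_covariates(graph$nodes, rasters)
  }
  flows <- tidy(nei) %>%
    dplyr::transmute(from = .data$site_a, to = .data$site_b,
                     flow = pmax(1 - .data$value, 1e-6))
  ranking <- rank_models_aicc(flows, graph, cfg$hypotheses)
  readr::write_csv(as_tibble(ranking), file.path(out_dir,
                                                 "gravity_models.csv"))
  best_name <- ranking$hypothesis[ranking$converged][1]
  best_h <- cfg$hypotheses[[which(vapply(cfg$hypotheses, function(h) h$name,
                                         "") == best_name)]]
  best_fit <- fit_gravity(flows, graph, best_h, mode = "REML")
  pruned <- predict_flow(best_fit, graph, cutoff = cfg$flow_cutoff,
                         max_km = cfg$predict_max_km)
  saturated_graph <- build_graph(nodes, method = "saturated")
  if (!is.null(rasters)) {
    saturated_graph <- extract_edge_covariates(saturated_graph, rasters)
    saturated_graph$nodes <- extract_node_covariates(saturated_graph$nodes,
                                                     rasters)
  }
  saturated <- predict_flow(best_fit, saturated_graph,
                            cutoff = cfg$flow_cutoff)
  readr::write_csv(pruned, file.path(out_dir, "flows_15km.csv"))
  readr::write_csv(saturated, file.path(out_dir, "flows_saturated.csv"))
  stage("gravity", list(best = best_name, n_edges = nrow(graph$edges),
                        n_flagged_pruned = sum(pruned$flagged)))

  # -- stage 7: AMOVA ------------------------------------------------------
  groupings <- cfg$groupings %||% list()
  if (!is.null(truth) && length(unique(truth$groups)) >= 2) {
    groupings$true_groups <- tibble(site_id = names(truth$groups),
                                    group = truth$groups)
  }
  if ("mu" %in% names(gm$sites)) {
    groupings$current_mu <- tibble(site_id = gm$sites$site_id,
                                   group = gm$sites$mu)
  }
  amova_tab <- NULL
  if (length(groupings) >= 2) {
    amova_tab <- compare_groupings(neutral, groupings)
    readr::write_csv(amova_tab, file.path(out_dir, "amova.csv"))
    stage("amova", list(n_groupings = length(groupings),
                        best = amova_tab$grouping[1]))
  } else {
    stage("amova", list(n_groupings = length(groupings), best = NA))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results <- list(gm = gm, neutral = neutral, candidates = candidates,
                  diversity = div, fst = fst, nei = nei, ne = ne_tab,
                  ranking = ranking, best_fit = best_fit,
                  flows_pruned = pruned, flows_saturated = saturated,
                  amova = amova_tab, truth = truth, out_dir = out_dir)
  attr(manifest, "results") <- results
  invisible(manifest)
}
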