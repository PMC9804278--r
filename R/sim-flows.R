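#' Simulate gravity-model flows on a spatial graph
#'
#' Generates edge flows from a known singly constrained gravity model:
#' `ln T_ij = b0 + b_w ln(w_ij) + sum b_v ln(v at origin) + sum b_c ln(c_ij)
#' + u_origin + eps_ij`, with the site effect `u ~ N(0, sigma_site^2)` and
#' residual `eps ~ N(0, sigma_resid^2)`. Coefficient names ending in
#' `_site` are at-site terms read from node covariates at the edge origin;
#' `dist` is the edge length; all other names are between-site edge
#' covariates. Every covariate must be strictly positive where a log is
#' taken.
#'
#' @param graph a [build_graph()] result whose edges carry the between-site
#'   covariates and whose nodes carry the at-site covariates.
#' @param truth named coefficient vector (see [default_gravity_truth()]).
#' @param sigma_site,sigma_resid random-effect and residual SDs.
#' @param seed integer seed.
#' @return a tibble of edges with the linear predictor, realised `ln_flow`
#'   and `flow`, plus the covariate columns used.
#' @export
simulate_gravity_flows <- function(graph, truth = default_gravity_truth(),
                                   sigma_site = 0.1, sigma_resid = 0.2,
                                   seed = 1L) {
  edges <- graph$edges
  nodes <- graph$nodes
  terms <- setdiff(names(truth), "intercept")
  lp <- rep(truth[["intercept"]], nrow(edges))
  for (tm in terms) {
    if (tm == "dist") {
      v <- edges$length_m
    } else if (grepl("_site$", tm)) {
      cov <- sub("_site$", "", tm)
      assert_that(cov %in% names(nodes),
                  paste0("missing at-site covariate: ", cov))
      v <- nodes[[cov]][match(edges$origin, nodes$id)]
    } else {
      assert_that(tm %in% names(edges),
                  paste0("missing between-site covariate: ", tm))
      v <- edges[[tm]]
    }
    assert_that(all(v > 0), paste0("covariate must be positive to log: ", tm))
    lp <- lp + truth[[tm]] * log(v)
  }
  set.seed(sub_seed(seed, "gravity_flows"))
  u <- setNames(rnorm(nrow(nodes), 0, sigma_site), nodes$id)
  eps <- rnorm(nrow(edges), 0, sigma_resid)
  ln_flow <- lp + u[edges$origin] + eps
  out <- edges
  out$linear_predictor <- lp
  out$ln_flow <- as.numeric(ln_flow)
  out$flow <- exp(out$ln_flow)
  as_tibble(out)
}
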