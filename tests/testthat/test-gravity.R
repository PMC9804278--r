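# shared toy landscape graph for gravity tests
make_gravity_graph <- function(n_nodes = 30, seed = 1, extent = 20000) {
  set.seed(seed)
  nodes <- tibble::tibble(id = sprintf("g%02d", seq_len(n_nodes)),
                          x = runif(n_nodes, 0, extent),
                          y = runif(n_nodes, 0, extent))
  g <- build_graph(nodes, "saturated")
  g$nodes$hli <- runif(n_nodes, 0.4, 1.2)
  g$nodes$cti <- runif(n_nodes, 5, 12)
  g$edges$stemp <- runif(nrow(g$edges), 14, 26)
  g$edges$fprecip <- runif(nrow(g$edges), 20, 60)
  g$edges$cti <- runif(nrow(g$edges), 5, 12)
  g
}

toy_truth <- c(intercept = 1.0, dist = -0.30, hli_site = -0.25,
               stemp = -0.50, fprecip = 0.20)
toy_hyp <- gravity_hypothesis("toy", at_site = "hli",
                              between = c("stemp", "fprecip"))

test_that("noise-free flows are interpolated exactly with smearing 1", {
  g <- make_gravity_graph(25, seed = 5)
  fl <- simulate_gravity_flows(g, toy_truth, sigma_site = 0,
                               sigma_resid = 0, seed = 2)
  fit <- fit_gravity(fl[, c("from", "to", "flow")], g, toy_hyp, mode = "REML")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["(Intercept)"]], 1.0, tolerance = 1e-6)
  expect_equal(est[["ln_dist"]], -0.30, tolerance = 1e-6)
  expect_equal(est[["ln_hli_site"]], -0.25, tolerance = 1e-6)
  expect_equal(est[["ln_stemp_btw"]], -0.50, tolerance = 1e-6)
  expect_equal(est[["ln_fprecip_btw"]], 0.20, tolerance = 1e-6)
  expect_equal(fit$smearing, 1, tolerance = 1e-8)

  # ML and REML agree in the no-random-effect limit
  fit_ml <- fit_gravity(fl[, c("from", "to", "flow")], g, toy_hyp,
                        mode = "ML")
  expect_equal(fit_ml$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("aicc follows its formula and limits", {
  # n = 100, k = 3, logLik = -50: AIC = 106, AICc = 106 + 24/96 = 106.25
  expect_equal(aicc_from_loglik(-50, 3, 100), 106.25)
  expect_error(aicc_from_loglik(-50, 3, 4), "undefined")
  # AICc converges to AIC as n grows
  expect_lt(aicc_from_loglik(-50, 5, 1e6) - (2 * 5 + 100), 0.01)
  # AICc >= AIC always
  expect_gte(aicc_from_loglik(-10, 4, 30), 2 * 4 + 20)
})

test_that("model ranking is consistent and handles duplicate hypotheses", {
  g <- make_gravity_graph(20, seed = 7)
  fl <- simulate_gravity_flows(g, toy_truth, sigma_site = 0.05,
                               sigma_resid = 0.15, seed = 3)
  hyps <- list(a = toy_hyp,
               b = gravity_hypothesis("toy_copy", at_site = "hli",
                                      between = c("stemp", "fprecip")),
               null = gravity_hypothesis("null"))
  rk <- rank_models_aicc(fl[, c("from", "to", "flow")], g, hyps)
  expect_equal(rk$aicc[rk$hypothesis == "toy"],
               rk$aicc[rk$hypothesis == "toy_copy"], tolerance = 1e-8)
  expect_equal(rk$delta_aicc[1], 0)
  expect_true(all(rk$delta_aicc >= 0))
  expect_equal(nrow(rk), 3L)
  expect_error(rank_models_aicc(fl, g, hyps["a"]), "two hypotheses")
})

test_that("coefficient recovery covers the truth at nominal rate", {
  g <- make_gravity_graph(24, seed = 11)   # 276 edges
  hits <- setNames(numeric(length(toy_truth)), names(toy_truth))
  reps <- 12
  for (r in seq_len(reps)) {
    fl <- simulate_gravity_flows(g, toy_truth, sigma_site = 0.10,
                                 sigma_resid = 0.20, seed = 100 + r)
    fit <- fit_gravity(fl[, c("from", "to", "flow")], g, toy_hyp,
                       mode = "REML")
    co <- fit$coefficients
    map <- c(intercept = "(Intercept)", dist = "ln_dist",
             hli_site = "ln_hli_site", stemp = "ln_stemp_btw",
             fprecip = "ln_fprecip_btw")
    for (nm in names(toy_truth)) {
      row <- co[co$term == map[[nm]], ]
      inside <- abs(toy_truth[[nm]] - row$estimate) <= row$ci_half_width
      hits[nm] <- hits[nm] + inside
    }
  }
  # nominal 95% coverage; allow generous sampling slack at 12 replicates
  expect_true(all(hits / reps >= 0.75))
})

test_that("the smearing factor approaches the lognormal mean", {
  g <- make_gravity_graph(60, seed = 13)   # 1770 edges
  sig <- 0.4
  fl <- simulate_gravity_flows(g, toy_truth, sigma_site = 0,
                               sigma_resid = sig, seed = 17)
  fit <- fit_gravity(fl[, c("from", "to", "flow")], g, toy_hyp,
                     mode = "REML")
  expect_lt(abs(fit$smearing - exp(sig^2 / 2)) / exp(sig^2 / 2), 0.05)
})

test_that("flow prediction back-transforms, clips, flags and prunes", {
  g <- make_gravity_graph(22, seed = 21)
  fl <- simulate_gravity_flows(g, toy_truth, sigma_site = 0.05,
                               sigma_resid = 0.1, seed = 5)
  fit <- fit_gravity(fl[, c("from", "to", "flow")], g, toy_hyp,
                     mode = "REML")
  pf <- suppressMessages(predict_flow(fit, g, cutoff = 0.85))
  expect_true(all(pf$flow <= 1 + 1e-12))
  expect_equal(pf$flagged, pf$flow >= 0.85)

  pf15 <- suppressMessages(predict_flow(fit, g, cutoff = 0.85, max_km = 15))
  expect_true(all(pf15$length_m <= 15000))
  expect_equal(attr(pf15, "variant"), "15 km")

  # training-graph prediction with random effects reproduces fitted values
  pf_re <- suppressMessages(
    predict_flow(fit, g, use_random_effects = TRUE))
  mf <- frogcu:::gravity_model_frame(fl[, c("from", "to", "flow")], g,
                                     toy_hyp, shifts = fit$shifts)
  expect_equal(pf_re$ln_pred, unname(stats::fitted(fit$model)),
               tolerance = 1e-8)
})

test_that("covariate shifts are recorded and reapplied at prediction", {
  g <- make_gravity_graph(18, seed = 31)
  g$edges$tempc <- runif(nrow(g$edges), -5, 10)   # crosses zero
  hyp <- gravity_hypothesis("shifted", between = "tempc")
  set.seed(3)
  fl <- tibble::tibble(from = g$edges$from, to = g$edges$to,
                       flow = exp(-0.2 * log(g$edges$length_m) +
                                    rnorm(nrow(g$edges), 0, 0.1)))
  fit <- fit_gravity(fl, g, hyp, mode = "REML")
  expect_gt(fit$shifts$tempc_btw, 0)
  pf <- suppressMessages(predict_flow(fit, g))
  expect_true(all(is.finite(pf$ln_pred)))

  # a target edge with the covariate missing is skipped with a warning
  g2 <- g
  g2$edges$tempc[1] <- NA
  expect_warning(pf2 <- suppressMessages(predict_flow(fit, g2)), "skipped")
  expect_equal(nrow(pf2), nrow(g2$edges) - 1L)
})

test_that("gravity fitting validates flows and hypothesis covariates", {
  g <- make_gravity_graph(10, seed = 41)
  fl <- tibble::tibble(from = g$edges$from, to = g$edges$to, flow = 0.5)
  fl$flow[1] <- 0
  expect_error(fit_gravity(fl, g, toy_hyp), "strictly positive")
  fl$flow[1] <- 0.5
  expect_error(fit_gravity(fl, g, gravity_hypothesis("bad",
                                                     between = "nope")),
               "missing between-site covariate")
})
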