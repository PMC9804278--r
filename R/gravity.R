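#' Define a gravity-model hypothesis
#'
#' A hypothesis names the at-site terms (production characteristics of the
#' origin node, `v`) and between-site terms (landscape matrix along the
#' edge, `c`) entering the model; geographic distance (`w`) is always
#' included, reflecting isolation by distance as the null expectation for
#' dispersal-limited amphibians.
#'
#' @param name hypothesis label.
#' @param at_site character vector of node covariate names.
#' @param between character vector of edge covariate names.
#' @return a `gravity_hypothesis` object.
#' @export
gravity_hypothesis <- function(name, at_site = character(0),
                               between = character(0)) {
  structure(list(name = name, at_site = at_site, between = between),
            class = "gravity_hypothesis")
}

#' Default hypothesis set for connectivity competition
#'
#' A compact hypothesis family for the simulated landscape: distance-only
#' null, temperature, moisture, productivity, and the combined
#' temperature-moisture structure.
#'
#' @return named list of [gravity_hypothesis()] objects.
#' @export
default_hypotheses <- function() {
  list(
    null = gravity_hypothesis("null"),
    temperature = gravity_hypothesis("temperature", at_site = "hli",
                                     between = "stemp"),
    moisture = gravity_hypothesis("moisture", at_site = "cti",
                                  between = c("fprecip", "cti")),
    productivity = gravity_hypothesis("productivity",
                                      at_site = c("hli", "cti")),
    temperature_moisture = gravity_hypothesis(
      "temperature_moisture", at_site = c("cti", "hli"),
      between = c("fprecip", "cti", "stemp"))
  )
}

# assemble the ln-scale model frame for a hypothesis; records the positive
# shifts applied before logging
gravity_model_frame <- function(flows, graph, hypothesis,
                                shifts = NULL) {
  edges <- graph$edges
  nodes <- graph$nodes
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (!is.null(flows)) {
    m <- match(key(edges$from, edges$to), key(flows$from, flows$to))
    edges$flow <- flows$flow[m]
  }
  covs <- list(dist = edges$length_m)
  for (v in hypothesis$at_site) {
    assert_that(v %in% names(nodes),
                paste0("missing at-site covariate on nodes: ", v))
    covs[[paste0(v, "_site")]] <- nodes[[v]][match(edges$origin, nodes$id)]
  }
  for (cv in hypothesis$between) {
    assert_that(cv %in% names(edges),
                paste0("missing between-site covariate on edges: ", cv))
    covs[[paste0(cv, "_btw")]] <- edges[[cv]]
  }
  new_shifts <- is.null(shifts)
  if (new_shifts) shifts <- list()
  df <- tibble(from = edges$from, to = edges$to, origin = edges$origin)
  for (nm in names(covs)) {
    x <- covs[[nm]]
    if (new_shifts) {
      mn <- min(x, na.rm = TRUE)
      shifts[[nm]] <- if (mn <= 0) 1 - mn else 0
    }
    sh <- shifts[[nm]] %||% 0
    xs <- x + sh
    bad <- !is.na(xs) & xs <= 0
    if (any(bad)) {
      stop(sprintf("non-positive value for '%s' after shift; cannot log", nm),
           call. = FALSE)
    }
    df[[paste0("ln_", nm)]] <- log(xs)
  }
  if (!is.null(flows)) df$ln_flow <- log(edges$flow)
  list(data = df, shifts = shifts,
       terms = paste0("ln_", names(covs)))
}

#' Fit a singly constrained gravity model
#'
#' Linearises the gravity equation by taking natural logs of the flow and
#' of every covariate and fits the linear mixed model
#' `ln(flow) ~ ln(dist) + sum ln(v at origin) + sum ln(c) + (1 | origin)`,
#' treating the edge origin site as a random intercept to absorb the
#' non-independence of edges sharing a site. Covariates that can be
#' non-positive (temperatures in degrees C, say) are shifted by
#' `1 - min` before the log; shifts are stored on the fit and re-applied at
#' prediction. ML fits are used for model competition, REML for reported
#' coefficients.
#'
#' @param flows tibble with `from`, `to`, `flow` (strictly positive; on the
#'   gene-flow scale `flow = 1 - Nei's D`).
#' @param graph a [build_graph()] result carrying the hypothesis covariates.
#' @param hypothesis a [gravity_hypothesis()].
#' @param mode `"REML"` or `"ML"`.
#' @return a `gravity_fit`: coefficient table, variance components
#'   `sigma_u` / `sigma_e`, information criteria (with
#'   `k = fixed effects + 2` variance parameters), Duan smearing factor
#'   `phi = mean(exp(residuals))`, shifts, residuals, convergence flag, and
#'   the underlying \pkg{lme4} fit.
#' @export
fit_gravity <- function(flows, graph, hypothesis, mode = c("REML", "ML")) {
  mode <- match.arg(mode)
  assert_that(inherits(hypothesis, "gravity_hypothesis"),
              "hypothesis must be a gravity_hypothesis")
  mf <- gravity_model_frame(flows, graph, hypothesis)
  df <- mf$data
  assert_that(all(!is.na(df$ln_flow)), "every edge needs a flow")
  assert_that(all(is.finite(df$ln_flow)), "flows must be strictly positive")

  ind <- df[, mf$terms, drop = FALSE]
  if (ncol(ind) >= 2) {
    r <- cor(as.data.frame(ind))
    idx <- pair_index(ncol(ind))
    high <- which(abs(r[idx]) >= 0.70)
    if (length(high) > 0) {
      warning(sprintf("correlated independents within hypothesis '%s': %s ~ %s (|r| = %.2f)",
                      hypothesis$name,
                      mf$terms[idx[high[1], 1]], mf$terms[idx[high[1], 2]],
                      abs(r[idx])[high[1]]))
    }
  }

  fml <- as.formula(paste("ln_flow ~", paste(mf$terms, collapse = " + "),
                          "+ (1 | origin)"))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = df, REML = (mode == "REML")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv <- fit@optinfo$conv$lme4$messages %||% character(0)
  converged <- !any(grepl("failed to converge", c(conv, msgs)))

  beta <- lme4::fixef(fit)
  if (length(beta) < length(mf$terms) + 1)
    stop("gravity design is rank deficient (unidentifiable)", call. = FALSE)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  half <- qnorm(0.975) * se
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "origin"][1]
  sigma_e <- vc$sdcor[vc$grp == "Residual"][1]
  res <- resid(fit)
  n <- nrow(df)
  k <- length(beta) + 2
  ll <- as.numeric(logLik(fit))

  coefs <- tibble(
    term = names(beta), estimate = as.numeric(beta),
    std_error = as.numeric(se), ci_half_width = as.numeric(half),
    excludes_zero = abs(beta) > half
  )
  structure(list(
    hypothesis = hypothesis, mode = mode, n = n, k = k,
    coefficients = coefs,
    sigma_u = sigma_u, sigma_e = sigma_e,
    log_lik = ll, aic = -2 * ll + 2 * k,
    aicc = aicc_from_loglik(ll, k, n),
    bic = -2 * ll + k * log(n),
    smearing = mean(exp(res)),
    residuals = as.numeric(res),
    shifts = mf$shifts, terms = mf$terms,
    converged = converged, messages = c(conv, msgs),
    model = fit
  ), class = "gravity_fit")
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat(sprintf("<gravity_fit:%s> %s, %d edges, AICc %.2f%s\n",
              x$mode, x$hypothesis$name, x$n, x$aicc,
              if (!x$converged) " (did not converge)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1) / (n - k - 1)`.
#'
#' @param log_lik model log-likelihood.
#' @param k number of estimated parameters (fixed effects including the
#'   intercept, plus the two variance components).
#' @param n number of observations.
#' @return the AICc value.
#' @export
aicc_from_loglik <- function(log_lik, k, n) {
  assert_that(n > k + 1, "AICc undefined: n must exceed k + 1")
  -2 * log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank gravity hypotheses by AICc
#'
#' Fits every hypothesis to the same edge set by maximum likelihood and
#' ranks by AICc. Non-converged fits are reported but excluded from the
#' best-model baseline.
#'
#' @param flows,graph as in [fit_gravity()].
#' @param hypotheses list of [gravity_hypothesis()] objects.
#' @return a `gravity_ranking` tibble: `hypothesis`, `n_params` (landscape
#'   terms including distance), `k`, `log_lik`, `aic`, `aicc`, `bic`,
#'   `converged`, `delta_aicc`; fitted objects in attribute `fits`.
#' @export
rank_models_aicc <- function(flows, graph, hypotheses) {
  assert_that(length(hypotheses) >= 2, "need at least two hypotheses")
  fits <- lapply(hypotheses, function(h)
    fit_gravity(flows, graph, h, mode = "ML"))
  tab <- dplyr::bind_rows(lapply(fits, function(f) tibble(
    hypothesis = f$hypothesis$name,
    n_params = length(f$terms),
    k = f$k, log_lik = f$log_lik,
    aic = f$aic, aicc = f$aicc, bic = f$bic,
    converged = f$converged
  )))
  best <- min(tab$aicc[tab$converged], na.rm = TRUE)
  tab$delta_aicc <- tab$aicc - best
  tab <- dplyr::arrange(tab, .data$aicc)
  attr(tab, "fits") <- fits
  class(tab) <- c("gravity_ranking", class(tab))
  tab
}

#' Predict gravity flows to a target graph
#'
#' Applies a fitted gravity model to the edges of a (possibly larger)
#' graph, at the population level (random effects zero), back-transforming
#' the ln-scale prediction with the Duan smearing factor:
#' `flow = phi * exp(X beta)`. Predictions above 1 are clipped (with a
#' logged count) since flow is on the `1 - Nei's D` scale. Edges missing a
#' required covariate are skipped with a warning.
#'
#' @param fit a `gravity_fit` (REML coefficients recommended).
#' @param target_graph a [build_graph()] result with the fit's covariates.
#' @param cutoff flows at or above this value are flagged as connected
#'   (0.85 corresponds to a predicted Nei's D of 0.15).
#' @param max_km optional maximum edge length (km); longer edges dropped.
#' @param use_random_effects include the fitted site intercepts (training
#'   graph only); smearing is omitted in that case so that the ln-scale
#'   prediction reproduces the fitted values.
#' @return a `flow_table` tibble: `from`, `to`, `length_m`, `ln_pred`,
#'   `flow`, `flagged`; attributes `cutoff`, `n_clipped`, `variant`.
#' @export
predict_flow <- function(fit, target_graph, cutoff = 0.85, max_km = NULL,
                         use_random_effects = FALSE) {
  assert_that(inherits(fit, "gravity_fit"), "fit must be a gravity_fit")
  edges <- target_graph$edges
  if (!is.null(max_km)) {
    target_graph$edges <- edges <- edges[edges$length_m <= max_km * 1000, ,
                                         drop = FALSE]
  }
  mf <- tryCatch(
    gravity_model_frame(NULL, target_graph, fit$hypothesis,
                        shifts = fit$shifts),
    error = function(e) stop(e)
  )
  df <- mf$data
  X <- as.matrix(df[, fit$terms, drop = FALSE])
  usable <- stats::complete.cases(X)
  if (any(!usable)) {
    warning(sprintf("%d edge(s) skipped: missing covariate value",
                    sum(!usable)))
  }
  beta <- fit$coefficients$estimate
  lp <- rep(NA_real_, nrow(df))
  lp[usable] <- beta[1] +
    X[usable, , drop = FALSE] %*% beta[-1]
  phi <- fit$smearing
  if (use_random_effects) {
    u <- lme4::ranef(fit$model)$origin
    uu <- setNames(u[, 1], rownames(u))
    lp <- lp + ifelse(df$origin %in% names(uu), uu[df$origin], 0)
    flow <- exp(lp)
  } else {
    flow <- phi * exp(lp)
  }
  n_clip <- sum(flow > 1, na.rm = TRUE)
  if (n_clip > 0) message(sprintf("%d flow prediction(s) clipped to 1", n_clip))
  flow <- pmin(flow, 1)
  out <- tibble(
    from = df$from, to = df$to,
    length_m = edges$length_m,
    ln_pred = lp, flow = flow,
    flagged = !is.na(flow) & flow >= cutoff
  )
  out <- out[usable, , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  attr(out, "n_clipped") <- n_clip
  attr(out, "variant") <- if (!is.null(max_km))
    sprintf("%g km", max_km) else "saturated"
  class(out) <- c("flow_table", class(out))
  out
}

#' @method tidy gravity_fit
#' @export
tidy.gravity_fit <- function(x, ...) x$coefficients

#' @method glance gravity_fit
#' @export
glance.gravity_fit <- function(x, ...) {
  tibble(
    hypothesis = x$hypothesis$name, mode = x$mode, n = x$n, k = x$k,
    log_lik = x$log_lik, aic = x$aic, aicc = x$aicc, bic = x$bic,
    sigma_u = x$sigma_u, sigma_e = x$sigma_e, smearing = x$smearing,
    converged = x$converged
  )
}
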