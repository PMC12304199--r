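#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the configured distributions and evaluates
#' the full pipeline (prevalence derivation, decision tree, Markov models,
#' CEA aggregation) for each draw. Draws failing validation are rejected and
#' redrawn with an incremented sub-seed (count recorded). Results are
#' reproducible given `seed`.
#'
#' @param params a validated parameter set with `psa_distributions`.
#' @param n number of probabilistic runs (default from
#'   `params$settings$n_psa`).
#' @param seed integer seed (default `params$settings$rng_seed`).
#' @return object of class `abdo_psa`: `draws` (data.frame of incremental
#'   outcomes and INMB per draw), `theta` (matrix of sampled parameter
#'   values), means, 95% percentile credible intervals,
#'   `prob_cost_effective` at the configured WTP, seed and rejection count.
#' @export
run_psa <- function(params, n = NULL, seed = NULL) {
  n <- n %||% params$settings$n_psa
  seed <- seed %||% params$settings$rng_seed
  stopifnot(n >= 1)
  wtp <- params$settings$wtp
  for (path in names(params$psa_distributions)) {
    psa_target_check(params, path, params$psa_distributions[[path]])
  }
  draws <- vector("list", n)
  thetas <- vector("list", n)
  rejected <- 0L
  for (i in seq_len(n)) {
    for (attempt in 0:100) {
      set.seed(psa_seed(seed, i, attempt))
      dr <- draw_parameter_set(params)
      ok <- tryCatch({
        validate_parameter_set(dr$params)
        cea <- evaluate_model(dr$params)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      rejected <- rejected + 1L
      if (attempt == 100) stop("PSA draw rejected 100 times; check distributions", call. = FALSE)
    }
    draws[[i]] <- data.frame(inc_cost = cea$incremental$cost,
                             inc_qaly = cea$incremental$qaly,
                             inc_ly = cea$incremental$ly,
                             inmb = cea$inmb)
    thetas[[i]] <- dr$theta
  }
  d <- do.call(rbind, draws)
  theta <- do.call(rbind, thetas)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  structure(list(
    draws = d, theta = theta, n = n, seed = seed, rejected = rejected, wtp = wtp,
    means = colMeans(d),
    ci = vapply(d, qs, numeric(2)),
    prob_cost_effective = mean(d$inmb > 0)
  ), class = "abdo_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic draws in
#' which screening has positive net monetary benefit.
#'
#' @param psa an `abdo_psa` result.
#' @param wtp_grid vector of thresholds (GBP/QALY).
#' @return data.frame `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(length(wtp_grid) >= 1)
  pce <- vapply(wtp_grid, function(l) {
    mean(l * psa$draws$inc_qaly - psa$draws$inc_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = pce)
}

#' Expected value of perfect information
#'
#' `mean over draws of the best achievable net benefit` minus `net benefit of
#' the best strategy on average`: the expected gain from resolving all
#' parameter uncertainty before deciding.
#'
#' @param nb matrix of net benefit, draws x strategies (use
#'   [psa_net_benefit()] to build it from an `abdo_psa`).
#' @return GBP per person (>= 0 up to floating point).
#' @export
evpi <- function(nb) {
  stopifnot(is.matrix(nb), ncol(nb) >= 2)
  mean(apply(nb, 1, max)) - max(colMeans(nb))
}

#' Net-benefit matrix for the two modelled strategies
#'
#' Current care is the reference (net benefit 0 by construction); screening's
#' net benefit per draw is its incremental NMB.
#'
#' @param psa an `abdo_psa` result.
#' @param wtp threshold; defaults to the PSA's configured WTP.
#' @return draws x 2 matrix (`current_care`, `screening`).
#' @export
psa_net_benefit <- function(psa, wtp = NULL) {
  wtp <- wtp %||% psa$wtp
  cbind(current_care = 0,
        screening = wtp * psa$draws$inc_qaly - psa$draws$inc_cost)
}

#' Expected value of partial perfect information for a parameter group
#'
#' Regression-based estimator: each strategy's net benefit is smoothed on the
#' group's sampled values with a generalised additive model (thin-plate
#' splines, smoothness by GCV); the fitted values estimate the conditional
#' expectation of net benefit given the group, and EVPPI is the mean of the
#' per-draw maximum of fitted values minus the maximum of their means. For
#' groups larger than four parameters the draws are projected onto their
#' first four principal components before smoothing.
#'
#' @param psa an `abdo_psa` result with stored `theta`.
#' @param group character vector of parameter paths (exact names or prefixes
#'   matched against `colnames(psa$theta)`).
#' @return list with `evppi` (GBP per person), `method`, `edf`, `n`.
#' @export
evppi <- function(psa, group) {
  nms <- colnames(psa$theta)
  cols <- nms[Reduce(`|`, lapply(group, function(g) startsWith(nms, g)))]
  if (!length(cols)) stop("parameter group matches no sampled parameters", call. = FALSE)
  X <- psa$theta[, cols, drop = FALSE]
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  nb <- psa_net_benefit(psa)[, "screening"]
  if (!ncol(X)) {
    return(list(evppi = 0, method = "constant-group", edf = 0, n = psa$n,
                note = "group has constant sampled values"))
  }
  method <- "gam-thinplate"
  if (ncol(X) > 4) {
    pc <- stats::prcomp(X, scale. = TRUE)
    X <- pc$x[, 1:4, drop = FALSE]
    method <- "gam-thinplate-pca4"
  }
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$nb <- nb
  kdim <- max(3, min(10, floor(psa$n / (4 * ncol(X)))))
  form <- stats::as.formula(paste("nb ~",
    paste(sprintf("s(x%d, k = %d)", seq_len(ncol(X)), kdim), collapse = " + ")))
  fit <- mgcv::gam(form, data = df, method = "GCV.Cp")
  g <- stats::fitted(fit)
  ## strategies: current care's conditional NB is identically 0
  v <- mean(pmax(g, 0)) - max(mean(g), 0)
  list(evppi = max(v, 0), method = method, edf = sum(fit$edf), n = psa$n)
}
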