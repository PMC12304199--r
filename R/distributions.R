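#' Define a sampling distribution for a model parameter
#'
#' Distributions attach to parameter paths (dotted keys into the parameter
#' set) and drive the probabilistic sensitivity analysis. Supported kinds:
#' `fixed` (degenerate, `value`), `beta` (`alpha`, `beta`; for probabilities),
#' `gamma` (`shape`, `scale`; for costs and rates), `lognormal`
#' (`meanlog`, `sdlog`; for ratios and dwell times) and `dirichlet`
#' (`alpha`, a vector; for stage/size simplexes).
#'
#' @param kind one of `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet"`.
#' @param ... named numeric parameters for the chosen kind.
#' @return an object of class `abdo_distribution`.
#' @examples
#' distribution("beta", alpha = 2, beta = 2)
#' distribution("fixed", value = 0.5)
#' @export
distribution <- function(kind, ...) {
  d <- structure(list(kind = kind, params = list(...)),
                 class = "abdo_distribution")
  validate_distribution(d)
  d
}

validate_distribution <- function(d, path = "distribution") {
  p <- d$params
  ok <- switch(d$kind,
    fixed     = length(p) == 1 && !is.null(p$value) && is.finite(p$value),
    beta      = is_scalar_number(p$alpha) && is_scalar_number(p$beta) &&
                p$alpha > 0 && p$beta > 0,
    gamma     = is_scalar_number(p$shape) && is_scalar_number(p$scale) &&
                p$shape > 0 && p$scale > 0,
    lognormal = is_scalar_number(p$meanlog) && is_scalar_number(p$sdlog) &&
                p$sdlog > 0,
    dirichlet = is.numeric(p$alpha) && length(p$alpha) >= 2 && all(p$alpha > 0),
    stop(sprintf("unknown distribution kind '%s' at '%s'", d$kind, path),
         call. = FALSE)
  )
  if (!isTRUE(ok)) {
    abort_validation(path, sprintf("invalid parameters for %s distribution", d$kind))
  }
  invisible(d)
}

## One draw from a distribution object (uses the current RNG state).
draw_distribution <- function(d) {
  p <- d$params
  switch(d$kind,
    fixed     = p$value,
    beta      = stats::rbeta(1, p$alpha, p$beta),
    gamma     = stats::rgamma(1, shape = p$shape, scale = p$scale),
    lognormal = stats::rlnorm(1, p$meanlog, p$sdlog),
    dirichlet = { g <- stats::rgamma(length(p$alpha), shape = p$alpha); g / sum(g) }
  )
}

## Moment-matched constructors used by the synthetic generator --------------

beta_from_mean <- function(mean, size = 50) {
  mean <- min(max(mean, 1e-6), 1 - 1e-6)
  distribution("beta", alpha = mean * size, beta = (1 - mean) * size)
}

gamma_from_mean_cv <- function(mean, cv = 0.2) {
  shape <- 1 / cv^2
  distribution("gamma", shape = shape, scale = mean / shape)
}

lognormal_from_mean_cv <- function(mean, cv = 0.2) {
  sdlog <- sqrt(log(1 + cv^2))
  distribution("lognormal", meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

dirichlet_from_mean <- function(mean, size = 100) {
  distribution("dirichlet", alpha = pmax(mean, 1e-4) * size)
}
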