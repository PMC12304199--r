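#' Combine per-cohort outcomes into a population result
#'
#' Weight-averages per-person outcomes across age/sex cohorts to reassemble
#' the eligible screening population.
#'
#' @param outcomes numeric vector (or data.frame of numeric columns), one
#'   entry/row per cohort.
#' @param weights cohort weights summing to 1.
#' @return weighted average (scalar, or named vector for data.frame input).
#' @export
combine_weighted <- function(outcomes, weights) {
  if (abs(sum(weights) - 1) > 1e-9) stop("cohort weights must sum to 1", call. = FALSE)
  if (is.data.frame(outcomes)) {
    if (nrow(outcomes) != length(weights)) stop("weight/outcome length mismatch", call. = FALSE)
    vapply(outcomes, function(col) sum(col * weights), numeric(1))
  } else {
    if (length(outcomes) != length(weights)) stop("weight/outcome length mismatch", call. = FALSE)
    sum(outcomes * weights)
  }
}

#' Incremental cost-effectiveness ratio with dominance codes
#'
#' @param inc_cost incremental cost (GBP per person).
#' @param inc_qaly incremental QALYs per person.
#' @return list with `value` (GBP/QALY or `NA`) and `code`: `"ratio"`,
#'   `"dominant"` (cheaper and more effective), `"dominated"` (costlier and
#'   less effective), `"ratio_southwest"` (both negative; the ratio is a
#'   savings-per-QALY-forgone trade-off) or `"undefined"` (zero QALY
#'   increment with nonzero cost).
#' @export
icer <- function(inc_cost, inc_qaly) {
  if (inc_qaly == 0) {
    if (inc_cost == 0) return(list(value = 0, code = "ratio"))
    return(list(value = NA_real_, code = "undefined"))
  }
  if (inc_cost <= 0 && inc_qaly > 0) return(list(value = inc_cost / inc_qaly, code = "dominant"))
  if (inc_cost >= 0 && inc_qaly < 0) return(list(value = inc_cost / inc_qaly, code = "dominated"))
  code <- if (inc_cost < 0 && inc_qaly < 0) "ratio_southwest" else "ratio"
  list(value = inc_cost / inc_qaly, code = code)
}

#' Incremental net monetary benefit
#'
#' `wtp * inc_qaly - inc_cost`: positive when the intervention is
#' cost-effective at the willingness-to-pay threshold.
#'
#' @inheritParams icer
#' @param wtp willingness to pay per QALY (GBP, > 0).
#' @return GBP per person.
#' @export
inmb <- function(inc_cost, inc_qaly, wtp) {
  stopifnot(wtp > 0)
  wtp * inc_qaly - inc_cost
}

#' Maximum justifiable screening cost
#'
#' The per-person screening cost at which the incremental net monetary
#' benefit falls to zero. Screen cost passes one-for-one into incremental
#' cost, so the answer is the current mean screen cost plus the current INMB.
#'
#' @param base_screen_cost current mean cost per screen (GBP).
#' @param inmb current incremental net monetary benefit (GBP per person).
#' @return GBP per screen.
#' @export
max_justifiable_cost <- function(base_screen_cost, inmb) {
  base_screen_cost + inmb
}

#' Per-disease decomposition of the incremental net monetary benefit
#'
#' Each modelled disease contributes its prevalence-weighted incremental net
#' benefit (Markov-phase costs and QALYs, diagnostic work-up, and its
#' positive-vs-negative screen cost delta); secondary-finding categories
#' contribute their diagnostic costs (and any scenario utility decrement);
#' the remaining "no disease" row carries the universal negative-screen base
#' cost and the radiation harm. Contributions sum to the total INMB (checked
#' at 1e-6 when the result is built).
#'
#' @param cea an `abdo_cea` result from [evaluate_model()].
#' @return data.frame with `organ`, `type`, `contribution` (GBP per person).
#' @export
decompose_by_disease <- function(cea) {
  stopifnot(inherits(cea, "abdo_cea"))
  cea$decomposition
}

#' Epidemiological outputs per 100,000 screened
#'
#' Lifetime cumulative deaths from each modelled disease prevented by
#' screening, and additional diagnoses made (screening can increase
#' diagnoses by detecting cases in people who would otherwise die of other
#' causes before symptomatic presentation), scaled per 100,000 screened.
#'
#' @param cea an `abdo_cea` result.
#' @param scale population scale (default 100,000; results stored at 1e5 are
#'   rescaled).
#' @return data.frame with per-disease counts.
#' @export
epi_outputs <- function(cea, scale = 1e5) {
  stopifnot(inherits(cea, "abdo_cea"))
  e <- cea$epi
  e$deaths_prevented_per_100k <- e$deaths_prevented_per_100k * scale / 1e5
  e$additional_cases_per_100k <- e$additional_cases_per_100k * scale / 1e5
  if (scale != 1e5) {
    names(e) <- sub("per_100k", paste0("per_", format(scale, scientific = FALSE)), names(e))
  }
  e
}
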