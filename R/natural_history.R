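#' Convert a mean sojourn (dwell) time to an annual transition probability
#'
#' Assumes a constant hazard within the stage, so a mean sojourn of `dwell`
#' years corresponds to an annual probability `1 - exp(-1/dwell)`.
#'
#' @param dwell mean sojourn time in years (> 0); vectorised.
#' @return annual probability in (0, 1).
#' @examples
#' sojourn_to_annual_probability(1) # 1 - exp(-1) ~ 0.632
#' @export
sojourn_to_annual_probability <- function(dwell) {
  if (any(!is.finite(dwell) & !is.infinite(dwell)) || any(dwell <= 0)) {
    stop("dwell time must be > 0", call. = FALSE)
  }
  1 - exp(-1 / dwell)
}

#' Calibrate control-arm symptomatic diagnosis probabilities
#'
#' Finds per-stage annual symptomatic-diagnosis probabilities `d` such that a
#' cohort entering preclinical stage I and progressing with the annual
#' probabilities implied by the dwell times reproduces the observed
#' stage-at-diagnosis distribution. Within each cycle diagnosis (probability
#' `d_s`) pre-empts progression (probability `(1-d_s) p_s`), so an entrant
#' into stage s is diagnosed there with probability
#' `pi_s = d_s / (d_s + (1-d_s) p_s)`. Stages I-III are solved sequentially by
#' bracketed root finding so the unconditional share diagnosed at stage s
#' matches the target; the stage-IV diagnosis probability is taken from the
#' stage-IV dwell time (mean preclinical time to symptomatic presentation),
#' and conservation then delivers the stage-IV share. The chain conditions on
#' surviving other causes.
#'
#' @param nh a cancer disease block (dwell_time, current_stage_distribution).
#' @param tol convergence tolerance on the achieved distribution.
#' @return numeric length-4 vector of annual diagnosis probabilities.
#' @export
calibrate_diagnosis_rates <- function(nh, tol = 1e-9) {
  target <- nh$current_stage_distribution
  check_simplex(target, "current_stage_distribution", tol = 1e-6)
  p <- sojourn_to_annual_probability(nh$dwell_time)
  d <- numeric(4)
  entrants <- 1
  for (s in 1:3) {
    want <- target[s] / entrants        # required P(diagnosed in stage s | entered s)
    if (want >= 1 - 1e-12) {
      d[s] <- 1 - 1e-12
    } else if (want <= 1e-15) {
      d[s] <- 0
    } else {
      f <- function(x) x / (x + (1 - x) * p[s]) - want
      if (f(1e-14) > 0 || f(1 - 1e-14) < 0) {
        stop(sprintf("calibration infeasible for stage %s", STAGES[s]), call. = FALSE)
      }
      d[s] <- stats::uniroot(f, c(1e-14, 1 - 1e-14), tol = tol)$root
    }
    entrants <- entrants - target[s]
    if (entrants < -1e-9) stop(sprintf("calibration infeasible for stage %s", STAGES[s]), call. = FALSE)
    entrants <- max(entrants, 0)
  }
  d[4] <- sojourn_to_annual_probability(nh$dwell_time[4])
  names(d) <- STAGES
  d
}

#' Screen-detectable prevalence and stage distribution at screening
#'
#' Length-biased sojourn approximation: the cross-sectional probability of
#' harbouring a preclinical stage-s cancer equals the rate of entry into
#' stage s times the expected (effective) sojourn in that stage, where the
#' sojourn reflects both progression (rate `1/dwell_s`) and exit through
#' symptomatic diagnosis (rate `-log(1 - d_s)` from the calibrated annual
#' probabilities; the stage-IV sojourn additionally competes with cancer
#' death). Detection further requires the scan to cover the organ and the
#' lesion to be visible, so per-stage detectable prevalence is
#' `entry_s * sojourn_s * sensitivity_s * coverage`. Competing other-cause
#' mortality is ignored inside this approximation (second order at these
#' sojourn lengths) but applied in the cohort models.
#'
#' @param nh a cancer disease block.
#' @param age attained age at screening.
#' @param sex `"male"` or `"female"`.
#' @param diagnosis_rates optional pre-computed output of
#'   [calibrate_diagnosis_rates()] (recomputed if omitted).
#' @return list with `prevalence` (total detectable probability),
#'   `stage_distribution` (length-4 shares among detected; `NA` with
#'   `degenerate = TRUE` when prevalence is 0), `per_stage` prevalence.
#' @export
screen_detectable_prevalence <- function(nh, age, sex, diagnosis_rates = NULL) {
  d <- diagnosis_rates %||% calibrate_diagnosis_rates(nh)
  k <- screen_detect_kernel(nh, d)
  inc <- age_sex_lookup(age_sex_matrix(nh$incidence), age, sex)
  per_stage <- inc * k$per_stage_kernel * (nh$prevalence_multiplier %||% 1)
  prev <- sum(per_stage)
  check_prob(min(prev, 1), "screen_detectable_prevalence")
  if (prev <= 0) {
    list(prevalence = 0, stage_distribution = rep(NA_real_, 4),
         per_stage = per_stage, degenerate = TRUE)
  } else {
    list(prevalence = prev, stage_distribution = per_stage / prev,
         per_stage = per_stage, degenerate = FALSE)
  }
}

## Age-free part of the prevalence closed form: per-stage expected detectable
## person-years per unit incidence. Entry into stage s+1 = entry into s times
## the probability of progressing before symptomatic diagnosis.
screen_detect_kernel <- function(nh, d) {
  lambda <- 1 / nh$dwell_time                      # progression rate (stage IV: presentation rate)
  delta <- -log(pmax(1 - d, 1e-300))               # symptomatic diagnosis rate
  mu4 <- -log(pmax(1 - nh$cancer_mortality[4], 1e-300))  # cancer death, undiagnosed stage IV
  sojourn <- c(1 / (lambda[1:3] + delta[1:3]),
               1 / (delta[4] + mu4))
  p_progress <- c(lambda[1:3] / (lambda[1:3] + delta[1:3]), 0)
  entry <- cumprod(c(1, p_progress[1:3]))          # relative entry rates per unit incidence
  kern <- entry * sojourn * nh$sensitivity * nh$coverage
  list(per_stage_kernel = kern, entry = entry, sojourn = sojourn)
}
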