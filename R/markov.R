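## Lifetime annual-cycle cohort Markov engine.
##
## Models are lists: states, alive index, a within-disease transition matrix
## P_dis (rows = alive states, columns = all states), an other-cause annual
## death probability function of age, per-state costs, per-state utility
## multipliers applied to the age-specific baseline utility, optional one-off
## transition costs, and state tags. Other-cause mortality composes
## multiplicatively: with probability q(age) an alive state moves to
## dead_other, otherwise the disease transition applies. Disease transitions
## themselves are built from additive competing risks and are checked for
## probability overflow.

other_cause_fn <- function(params, sex, hr = 1) {
  mat <- age_sex_matrix(params$other_cause_mortality)
  horizon <- params$settings$horizon_age
  function(age) {
    if (age >= horizon) return(1) # force absorption at the horizon
    q <- age_sex_lookup(mat, age, sex)
    min(1 - (1 - q)^hr, 1)
  }
}

baseline_utility_fn <- function(params, sex) {
  mat <- age_sex_matrix(params$baseline_utilities)
  function(age) age_sex_lookup(mat, age, sex)
}

## within-disease annual transition matrix for a cancer model
## states: U1..U4, D1y1, D1y2, ..., D4y1, D4y2, dead_cancer, dead_other
cancer_states <- function() {
  c(paste0("undiag_", STAGES),
    as.vector(t(outer(STAGES, c("y1", "y2plus"), function(s, b) paste0("diag_", s, "_", b)))),
    "dead_cancer", "dead_other")
}

cancer_disease_matrix <- function(p_progress, d_diag, mortality, mort_mult = rep(1, 4)) {
  st <- cancer_states()
  n <- length(st)
  P <- matrix(0, 12, n, dimnames = list(st[1:12], st))
  m <- pmin(mortality * mort_mult, 1)
  iU <- function(s) s
  iD <- function(s, b) 4 + 2 * (s - 1) + b
  for (s in 1:4) {
    d <- d_diag[s]
    if (s < 4) {
      pr <- (1 - d) * p_progress[s]
      if (d + pr > 1 + 1e-12) {
        stop(sprintf("competing risks exceed 1 in state %s", st[iU(s)]), call. = FALSE)
      }
      P[iU(s), iD(s, 1)] <- d
      P[iU(s), iU(s + 1)] <- pr
      P[iU(s), iU(s)] <- 1 - d - pr
    } else {
      dm <- (1 - d) * m[4] # undiagnosed stage IV dies at the diagnosed-IV rate
      P[iU(4), iD(4, 1)] <- d
      P[iU(4), "dead_cancer"] <- dm
      P[iU(4), iU(4)] <- 1 - d - dm
    }
    P[iD(s, 1), "dead_cancer"] <- m[s]
    P[iD(s, 1), iD(s, 2)] <- 1 - m[s]
    P[iD(s, 2), "dead_cancer"] <- m[s]
    P[iD(s, 2), iD(s, 2)] <- 1 - m[s]
  }
  P
}

#' Build a cancer cohort Markov model
#'
#' States are undiagnosed stages I-IV, diagnosed stages I-IV split by time
#' since diagnosis (first year / subsequent years), death from the cancer and
#' death from other causes. Undiagnosed states carry baseline utility and no
#' treatment cost; diagnosis triggers stage-specific treatment costs and
#' utility multipliers. Undiagnosed disease progresses at the dwell-time
#' probabilities and presents symptomatically at the calibrated diagnosis
#' probabilities; undiagnosed stage IV additionally dies at the diagnosed
#' stage-IV rate. In the screening arm a per-stage mortality multiplier
#' (scenario knob, default 1) applies to diagnosed states.
#'
#' @param nh cancer disease block.
#' @param arm `"screening"` or `"control"`.
#' @param params the parameter set (rewards, mortality and utility tables).
#' @param sex cohort sex.
#' @param diagnosis_rates optional output of [calibrate_diagnosis_rates()].
#' @return a model list for [run_cohort()].
#' @export
build_cancer_model <- function(nh, arm = c("screening", "control"), params, sex,
                               diagnosis_rates = NULL) {
  arm <- match.arg(arm)
  d <- diagnosis_rates %||% calibrate_diagnosis_rates(nh)
  p <- sojourn_to_annual_probability(nh$dwell_time)
  mm <- if (arm == "screening") params$modifiers$screening_mortality_multiplier else rep(1, 4)
  P <- cancer_disease_matrix(p, d, nh$cancer_mortality, mm)
  st <- cancer_states()
  cost <- stats::setNames(numeric(length(st)), st)
  umult <- stats::setNames(c(rep(1, 4), numeric(8), 0, 0), st)
  tc <- params$treatment_cost * nh$cost_multiplier # 4x2, recycled by stage rows
  for (s in 1:4) {
    cost[4 + 2 * s - 1] <- tc[s, 1]
    cost[4 + 2 * s] <- tc[s, 2]
    umult[4 + 2 * s - 1] <- params$utility_multiplier[s, 1]
    umult[4 + 2 * s] <- params$utility_multiplier[s, 2]
  }
  tags <- data.frame(
    state = st,
    diagnosed = c(rep(FALSE, 4), rep(TRUE, 8), NA, NA),
    stage = c(STAGES, rep(STAGES, each = 2), NA, NA),
    entry_band = c(rep(FALSE, 4), rep(c(TRUE, FALSE), 4), NA, NA),
    dead_cause = c(rep(NA, 12), "cancer", "other")
  )
  list(states = st, alive = 1:12, dead_other = which(st == "dead_other"),
       P_dis = P, q_fun = other_cause_fn(params, sex),
       state_cost = cost, utility_mult = umult,
       base_utility = baseline_utility_fn(params, sex),
       transition_cost = NULL, tags = tags, arm = arm)
}

## AAA states shared by both arms; the arms differ in what happens at large
## size: detected disease is electively repaired, undetected disease ruptures.
aaa_states <- function() c("small", "medium", "large", "post_repair", "dead_aaa", "dead_other")

aaa_disease_matrix <- function(ab, arm) {
  st <- aaa_states()
  P <- matrix(0, 4, 6, dimnames = list(st[1:4], st))
  tc <- matrix(0, 4, 6, dimnames = list(st[1:4], st))
  r <- ab$rupture_rate; g <- ab$growth
  es <- ab$emergency_repair$survival
  for (s in 1:2) { # small, medium: rupture else grow, identical in both arms
    grow <- (1 - r[s]) * g[s]
    P[s, "post_repair"] <- r[s] * es
    P[s, "dead_aaa"] <- r[s] * (1 - es)
    P[s, s + 1] <- grow
    P[s, s] <- 1 - r[s] - grow
    tc[s, "post_repair"] <- ab$emergency_repair$cost
  }
  if (arm == "screening") { # elective repair on reaching large
    om <- ab$elective_repair$operative_mortality
    P[3, "post_repair"] <- 1 - om
    P[3, "dead_aaa"] <- om
    tc[3, "post_repair"] <- ab$elective_repair$cost
    tc[3, "dead_aaa"] <- ab$elective_repair$cost
  } else { # undetected large: size-specific rupture hazard
    P[3, "post_repair"] <- r[3] * es
    P[3, "dead_aaa"] <- r[3] * (1 - es)
    P[3, 3] <- 1 - r[3]
    tc[3, "post_repair"] <- ab$emergency_repair$cost
  }
  P[4, 4] <- 1
  list(P = P, tc = tc)
}

#' Build the AAA cohort Markov model
#'
#' Three aneurysm size states (small 3.0-4.4, medium 4.5-5.4, large >= 5.5 cm)
#' plus post-repair and death states. In the screening arm detected AAA is
#' under surveillance (size-specific annual cost) and is electively repaired
#' on reaching the large state (operative mortality, one-off cost). In the
#' control arm the aneurysm is undetected and ruptures at size-specific
#' annual probabilities; rupture leads to emergency repair with a survival
#' probability (one-off cost charged for survivors).
#'
#' @param ab AAA disease block.
#' @inheritParams build_cancer_model
#' @return a model list for [run_cohort()].
#' @export
build_aaa_model <- function(ab, arm = c("screening", "control"), params, sex) {
  arm <- match.arg(arm)
  dm <- aaa_disease_matrix(ab, arm)
  st <- aaa_states()
  cost <- stats::setNames(numeric(6), st)
  if (arm == "screening") cost[1:2] <- ab$surveillance_cost[1:2]
  umult <- stats::setNames(c(1, 1, 1, 1, 0, 0), st)
  tags <- data.frame(
    state = st,
    diagnosed = c(rep(arm == "screening", 3), NA, NA, NA),
    stage = c(AAA_SIZES, NA, NA, NA),
    entry_band = FALSE,
    dead_cause = c(rep(NA, 4), "aaa", "other")
  )
  list(states = st, alive = 1:4, dead_other = 6L,
       P_dis = dm$P, q_fun = other_cause_fn(params, sex),
       state_cost = cost, utility_mult = umult,
       base_utility = baseline_utility_fn(params, sex),
       transition_cost = dm$tc, tags = tags, arm = arm)
}

#' Build the no-disease cohort Markov model
#'
#' Two states: alive (age-specific baseline utility, no incremental cost) and
#' dead from all causes.
#'
#' @inheritParams build_cancer_model
#' @return a model list for [run_cohort()].
#' @export
build_no_disease_model <- function(params, sex) {
  st <- c("alive", "dead_other")
  P <- matrix(c(1, 0), 1, 2, dimnames = list("alive", st))
  tags <- data.frame(state = st, diagnosed = NA, stage = NA,
                     entry_band = FALSE, dead_cause = c(NA, "other"))
  list(states = st, alive = 1L, dead_other = 2L,
       P_dis = P, q_fun = other_cause_fn(params, sex),
       state_cost = stats::setNames(c(0, 0), st),
       utility_mult = stats::setNames(c(1, 0), st),
       base_utility = baseline_utility_fn(params, sex),
       transition_cost = NULL, tags = tags, arm = "both")
}

## full annual transition matrix at a given age (other-cause death composed
## multiplicatively with the within-disease matrix)
model_transition <- function(model, age) {
  n <- length(model$states)
  P <- diag(n)
  dimnames(P) <- list(model$states, model$states)
  q <- model$q_fun(age)
  P[model$alive, ] <- (1 - q) * model$P_dis
  P[model$alive, model$dead_other] <- P[model$alive, model$dead_other] + q
  P
}

#' Run a cohort through a Markov model
#'
#' Iterates annual cycles from `start_age` to the horizon, accumulating
#' discounted and undiscounted costs, life years and QALYs with a trapezoidal
#' (half-cycle) occupancy correction; completed cycle k is discounted by
#' `(1+r)^-k`. One-off transition costs accrue on the flows that trigger
#' them. Row-stochasticity and occupancy conservation are verified every
#' cycle.
#'
#' @param model a model list from one of the builders (or hand-built with the
#'   same fields).
#' @param init initial state occupancy (sums to the cohort mass).
#' @param start_age age at the start of the first cycle.
#' @param settings list with `horizon_age`, `discount_rate_costs`,
#'   `discount_rate_qalys`.
#' @return list with `trace` ((cycles+1) x states occupancy) and `outcome`
#'   (discounted/undiscounted cost, QALYs, life years, deaths by cause,
#'   cumulative diagnoses by stage).
#' @export
run_cohort <- function(model, init, start_age, settings) {
  n_cycles <- settings$horizon_age - start_age
  stopifnot(n_cycles >= 1)
  S <- length(model$states)
  stopifnot(length(init) == S)
  mass <- sum(init)
  dfc <- discount_factors(settings$discount_rate_costs, n_cycles)
  dfu <- discount_factors(settings$discount_rate_qalys, n_cycles)
  trace <- matrix(0, n_cycles + 1, S, dimnames = list(NULL, model$states))
  trace[1, ] <- init
  x <- init
  dc <- uc <- dq <- uq <- dly <- uly <- 0
  diag_flow <- stats::setNames(numeric(4), STAGES)
  is_entry <- !is.na(model$tags$entry_band) & model$tags$entry_band &
    !is.na(model$tags$diagnosed) & model$tags$diagnosed
  undiag <- !is.na(model$tags$diagnosed) & !model$tags$diagnosed

  for (k in seq_len(n_cycles)) {
    age <- start_age + k - 1
    P <- model_transition(model, age)
    rs <- rowSums(P)
    if (any(abs(rs - 1) > 1e-9) || any(P < -1e-12)) {
      stop(sprintf("transition matrix not row-stochastic at cycle %d (age %d)", k, age),
           call. = FALSE)
    }
    flows <- x * P
    x_new <- colSums(flows)
    if (abs(sum(x_new) - mass) > 1e-9) {
      stop(sprintf("occupancy not conserved at cycle %d", k), call. = FALSE)
    }
    mid <- (x + x_new) / 2
    cost_k <- sum(mid * model$state_cost)
    if (!is.null(model$transition_cost)) {
      cost_k <- cost_k + sum(flows[model$alive, , drop = FALSE] *
                               model$transition_cost)
    }
    ly_k <- sum(mid[model$alive])
    q_k <- sum(mid * model$utility_mult) * model$base_utility(age)
    dc <- dc + dfc[k] * cost_k; uc <- uc + cost_k
    dq <- dq + dfu[k] * q_k;   uq <- uq + q_k
    dly <- dly + dfu[k] * ly_k; uly <- uly + ly_k
    if (any(is_entry)) {
      diag_in <- colSums(flows[undiag, is_entry, drop = FALSE])
      stg <- model$tags$stage[is_entry]
      for (j in seq_along(stg)) diag_flow[stg[j]] <- diag_flow[stg[j]] + diag_in[j]
    }
    x <- x_new
    trace[k + 1, ] <- x
  }
  dead <- !is.na(model$tags$dead_cause)
  deaths <- stats::setNames(x[dead] - trace[1, dead], model$tags$dead_cause[dead])
  list(trace = trace,
       outcome = list(discounted_cost = dc, discounted_qaly = dq, discounted_ly = dly,
                      undiscounted_cost = uc, undiscounted_qaly = uq, undiscounted_ly = uly,
                      deaths_by_cause = deaths, diagnoses_by_stage = diag_flow))
}

#' Expected screen-detected counts with exact Poisson intervals
#'
#' Computes, for each modelled disease, the cohort-weighted screen-detectable
#' prevalence, the expected number of detections among `scale` screened
#' people, and the exact Poisson 95% interval around that expectation, for
#' comparison against observed trial counts.
#'
#' @param params a validated parameter set.
#' @param scale number of people screened (default 4019).
#' @return data.frame with disease, prevalence, expected count and interval.
#' @export
validate_against_counts <- function(params, scale = 4019) {
  ctx <- pipeline_context(params)
  prev <- ctx$weighted_prevalence
  expected <- prev * scale
  lower <- ifelse(expected > 0, stats::qgamma(0.025, expected), 0)
  upper <- stats::qgamma(0.975, expected + 1)
  data.frame(disease = names(prev), prevalence = as.numeric(prev),
             expected = as.numeric(expected), lower = lower, upper = upper,
             row.names = NULL)
}
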