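# Independent oracles. Each reimplements the quantity under test by a
# different route (linear algebra, Monte-Carlo simulation, direct cohort
# bookkeeping) and never calls the code path it checks.

# Discounted trapezoidal reward over N cycles of a time-homogeneous chain,
# via the truncated fundamental-matrix form:
#   sum_k d^k (x_{k-1} + x_k)/2 . r  =  x0 (S1 + S2)/2 r,
#   S1 = d (I - (dQ)^N)(I - dQ)^-1,  S2 = (dQ)(I - (dQ)^N)(I - dQ)^-1
oracle_discounted_reward <- function(Q, x0, reward, rate, n_cycles) {
  S <- nrow(Q)
  d <- 1 / (1 + rate)
  dQ <- d * Q
  pw <- diag(S)
  for (i in seq_len(n_cycles)) pw <- pw %*% dQ
  core <- (diag(S) - pw) %*% solve(diag(S) - dQ)
  drop(x0 %*% ((d * core + dQ %*% core) / 2) %*% reward)
}

random_stochastic_matrix <- function(S) {
  m <- matrix(stats::rexp(S * S), S, S)
  m / rowSums(m)
}

# wrap an arbitrary time-homogeneous chain as an engine model (no other-cause
# mortality; all states counted alive so only cost/utility rewards are used)
chain_as_model <- function(Q, reward) {
  S <- nrow(Q)
  st <- paste0("s", seq_len(S))
  dimnames(Q) <- list(st, st)
  list(states = st, alive = seq_len(S), dead_other = S,
       P_dis = Q, q_fun = function(age) 0,
       state_cost = reward, utility_mult = stats::setNames(numeric(S), st),
       base_utility = function(age) 1,
       transition_cost = NULL,
       tags = data.frame(state = st, diagnosed = NA, stage = NA,
                         entry_band = FALSE, dead_cause = NA),
       arm = "oracle")
}

# Monte-Carlo microsimulation of screen-detectable prevalence: each preclinical
# case draws competing exponential sojourns (progression vs symptomatic
# diagnosis; cancer death in stage IV); its expected contribution to
# cross-sectional detectable prevalence is incidence times the
# sensitivity/coverage-weighted time spent per stage.
microsim_prevalence <- function(nh, age, sex, n = 1e6, seed = 1) {
  set.seed(seed)
  d <- calibrate_diagnosis_rates(nh)
  lambda <- 1 / nh$dwell_time
  delta <- -log(pmax(1 - d, 1e-300))
  mu4 <- -log(pmax(1 - nh$cancer_mortality[4], 1e-300))
  inc <- nh$incidence$value[nh$incidence$age == age & nh$incidence$sex == sex]
  alive_in_stage <- rep(TRUE, n)
  obs <- numeric(n)
  for (s in 1:4) {
    rate_exit <- if (s < 4) lambda[s] + delta[s] else delta[4] + mu4
    t_s <- stats::rexp(n, rate_exit)
    obs <- obs + alive_in_stage * t_s * nh$sensitivity[s] * nh$coverage
    if (s < 4) {
      progressed <- stats::runif(n) < lambda[s] / rate_exit
      alive_in_stage <- alive_in_stage & progressed
    }
  }
  list(prevalence = inc * mean(obs), se = inc * stats::sd(obs) / sqrt(n))
}

# hand-built PSA object for estimator-level tests
psa_toy <- function(inc_cost, inc_qaly, wtp = 20000) {
  d <- data.frame(inc_cost = inc_cost, inc_qaly = inc_qaly,
                  inc_ly = inc_qaly, inmb = wtp * inc_qaly - inc_cost)
  structure(list(draws = d, theta = NULL, n = nrow(d), seed = 0, rejected = 0,
                 wtp = wtp, means = colMeans(d),
                 prob_cost_effective = mean(d$inmb > 0)),
            class = "abdo_psa")
}

# Forward cohort bookkeeping of the calibration chain (no deaths): a unit
# cohort enters preclinical stage I; per cycle, diagnosis pre-empts
# progression. Returns the normalised stage-at-diagnosis distribution.
forward_stage_at_diagnosis <- function(p_progress, d_diag, max_cycles = 20000) {
  u <- c(1, 0, 0, 0)
  diag <- numeric(4)
  for (k in seq_len(max_cycles)) {
    dflow <- u * d_diag
    diag <- diag + dflow
    pflow <- u * (1 - d_diag) * c(p_progress[1:3], 0)
    u <- u - dflow - pflow + c(0, pflow[1:3])
    if (sum(u) < 1e-14) break
  }
  diag / sum(diag)
}
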