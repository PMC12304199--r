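## Fast multi-cohort evaluation of the full pipeline
## (prevalence -> decision tree -> Markov models -> CEA aggregation).
##
## All age/sex cohorts are propagated simultaneously: each cycle the alive
## occupancy block (cohorts x states) is scaled by cohort-specific other-cause
## survival and multiplied by the age-invariant within-disease transition
## matrix. This reproduces the per-cohort engine in markov.R exactly (tested)
## at a fraction of the cost, which is what makes 2000-run probabilistic
## analyses practical.

effective_cohorts <- function(params) {
  ch <- params$cohorts
  keep <- ch$start_age >= params$age_range[1] & ch$start_age <= params$age_range[2]
  ch <- ch[keep, , drop = FALSE]
  if (!nrow(ch) || sum(ch$weight) <= 0) stop("no cohorts in the configured age range", call. = FALSE)
  ch$weight <- ch$weight / sum(ch$weight)
  rownames(ch) <- NULL
  ch
}

## per-evaluation context: cohort-cycle mortality, utilities, masks, discounts
pipeline_context <- function(params) {
  coh <- effective_cohorts(params)
  n_c <- nrow(coh)
  horizon <- params$settings$horizon_age
  N <- horizon - min(coh$start_age)
  mort <- age_sex_matrix(params$other_cause_mortality)
  butil <- age_sex_matrix(params$baseline_utilities)
  Q <- U <- M <- matrix(0, n_c, N)
  for (k in seq_len(N)) {
    age <- coh$start_age + k - 1
    alive_window <- age < horizon
    Q[, k] <- ifelse(alive_window, age_sex_lookup(mort, age, coh$sex), 1)
    U[, k] <- age_sex_lookup(butil, age, coh$sex)
    M[, k] <- as.numeric(alive_window)
  }
  dfc <- discount_factors(params$settings$discount_rate_costs, N)
  dfu <- discount_factors(params$settings$discount_rate_qalys, N)

  ## decision-tree ingredients, vectorised over cohorts
  cancers <- list(); aaa <- NULL
  for (nm in names(params$diseases)) {
    d <- params$diseases[[nm]]
    if (d$type == "cancer") {
      dr <- calibrate_diagnosis_rates(d)
      kern <- screen_detect_kernel(d, dr)
      ksum <- sum(kern$per_stage_kernel)
      prev <- age_sex_lookup(age_sex_matrix(d$incidence), coh$start_age, coh$sex) *
        ksum * d$prevalence_multiplier
      w <- if (ksum > 0) kern$per_stage_kernel / ksum else numeric(4)
      w_screen <- apply_stage_modifiers(w, d, params$modifiers)
      cancers[[nm]] <- list(block = d, diagnosis_rates = dr, prevalence = prev,
                            stage_screen = w_screen,
                            pathway_cost = diagnostic_cost(d$pathway_id, params$pathways))
    } else {
      prev <- age_sex_lookup(age_sex_matrix(d$prevalence), coh$start_age, coh$sex) *
        d$prevalence_multiplier
      aaa <- list(name = nm, block = d, prevalence = prev,
                  pathway_cost = diagnostic_cost(d$pathway_id, params$pathways))
    }
  }
  secondary <- lapply(params$secondary, function(b) {
    list(organ = b$organ, category = b$category,
         prevalence = age_sex_lookup(age_sex_matrix(b$prevalence), coh$start_age, coh$sex),
         pathway_cost = if (b$category == "minor") 0
                        else diagnostic_cost(b$pathway_id, params$pathways))
  })

  prev_cancer <- if (length(cancers)) {
    do.call(cbind, lapply(cancers, `[[`, "prevalence"))
  } else matrix(0, n_c, 0)
  prev_aaa <- if (!is.null(aaa)) aaa$prevalence else numeric(n_c) * 0
  prev_sec <- if (length(secondary)) {
    do.call(cbind, lapply(secondary, `[[`, "prevalence"))
  } else matrix(0, n_c, 0)
  sec_positive <- vapply(secondary, function(b) b$category != "minor", logical(1))

  total <- rowSums(prev_cancer) + prev_aaa + rowSums(prev_sec)
  if (any(total > 1)) { # categories are mutually exclusive: renormalise overlap
    scl <- pmin(1, 1 / total)
    prev_cancer <- prev_cancer * scl; prev_aaa <- prev_aaa * scl; prev_sec <- prev_sec * scl
    for (nm in names(cancers)) cancers[[nm]]$prevalence <- prev_cancer[, nm]
    if (!is.null(aaa)) aaa$prevalence <- prev_aaa
    total <- pmin(total, 1)
  }
  p_positive <- rowSums(prev_cancer) + prev_aaa +
    (if (any(sec_positive)) rowSums(prev_sec[, sec_positive, drop = FALSE]) else 0)

  wprev <- c(colSums(coh$weight * prev_cancer),
             if (!is.null(aaa)) stats::setNames(sum(coh$weight * prev_aaa), aaa$name))

  list(cohorts = coh, n_c = n_c, N = N, Q = Q, U = U, M = M, dfc = dfc, dfu = dfu,
       cancers = cancers, aaa = aaa, secondary = secondary,
       prev_sec = prev_sec, sec_positive = sec_positive,
       p_positive = p_positive, no_disease_mass = 1 - rowSums(prev_cancer) - prev_aaa,
       weighted_prevalence = wprev)
}

## propagate all cohorts through one disease model; X0 is cohorts x states
run_cohorts_fast <- function(P_dis, X0, ctx, state_cost, utility_mult,
                             trans_cost_row = NULL, diag_probs = NULL,
                             disease_dead_col = NULL) {
  n_alive <- nrow(P_dis)
  S <- ncol(P_dis)
  dead_cols <- (n_alive + 1):S
  X <- X0
  n_c <- ctx$n_c
  dc <- dq <- dly <- numeric(n_c)
  diagnoses <- numeric(n_c)
  PA <- P_dis[, seq_len(n_alive), drop = FALSE]
  PD <- P_dis[, dead_cols, drop = FALSE]
  for (k in seq_len(ctx$N)) {
    q <- ctx$Q[, k]
    A <- X[, seq_len(n_alive), drop = FALSE]
    surv <- A * (1 - q)
    Xn <- X
    Xn[, seq_len(n_alive)] <- surv %*% PA
    Xn[, dead_cols] <- X[, dead_cols, drop = FALSE] + surv %*% PD
    do <- S # dead-other is always the last state
    Xn[, do] <- Xn[, do] + rowSums(A) * q
    mid <- (X + Xn) / 2
    msk <- ctx$M[, k]
    cost_k <- as.numeric(mid %*% state_cost)
    if (!is.null(trans_cost_row)) cost_k <- cost_k + as.numeric(surv %*% trans_cost_row)
    dc <- dc + ctx$dfc[k] * cost_k * msk
    dq <- dq + ctx$dfu[k] * as.numeric(mid %*% utility_mult) * ctx$U[, k] * msk
    dly <- dly + ctx$dfu[k] * rowSums(mid[, seq_len(n_alive), drop = FALSE]) * msk
    if (!is.null(diag_probs)) {
      diagnoses <- diagnoses + as.numeric(surv[, 1:4, drop = FALSE] %*% diag_probs)
    }
    X <- Xn
  }
  list(cost = dc, qaly = dq, ly = dly,
       disease_deaths = if (!is.null(disease_dead_col)) X[, disease_dead_col] else numeric(n_c),
       diagnoses = diagnoses, final = X)
}

run_cancer_arm <- function(info, params, ctx, arm) {
  nh <- info$block
  mm <- if (arm == "screening") params$modifiers$screening_mortality_multiplier else rep(1, 4)
  P <- cancer_disease_matrix(sojourn_to_annual_probability(nh$dwell_time),
                             info$diagnosis_rates, nh$cancer_mortality, mm)
  st <- cancer_states()
  cost <- stats::setNames(numeric(14), st)
  umult <- stats::setNames(c(rep(1, 4), numeric(10)), st)
  tc <- params$treatment_cost * nh$cost_multiplier
  for (s in 1:4) {
    cost[4 + 2 * s - 1] <- tc[s, 1]; cost[4 + 2 * s] <- tc[s, 2]
    umult[4 + 2 * s - 1] <- params$utility_multiplier[s, 1]
    umult[4 + 2 * s] <- params$utility_multiplier[s, 2]
  }
  X0 <- matrix(0, ctx$n_c, 14, dimnames = list(NULL, st))
  w <- info$stage_screen
  if (arm == "screening") {
    for (s in 1:4) X0[, 4 + 2 * s - 1] <- info$prevalence * w[s]
  } else {
    for (s in 1:4) X0[, s] <- info$prevalence * w[s]
  }
  out <- run_cohorts_fast(P, X0, ctx, cost, umult,
                          diag_probs = info$diagnosis_rates,
                          disease_dead_col = which(st == "dead_cancer"))
  if (arm == "screening") out$diagnoses <- out$diagnoses + info$prevalence
  out
}

run_aaa_arm <- function(info, params, ctx, arm) {
  ab <- info$block
  dm <- aaa_disease_matrix(ab, arm)
  st <- aaa_states()
  cost <- stats::setNames(numeric(6), st)
  if (arm == "screening") cost[1:2] <- ab$surveillance_cost[1:2]
  umult <- stats::setNames(c(1, 1, 1, 1, 0, 0), st)
  tc_row <- rowSums(dm$P[, , drop = FALSE] * dm$tc)
  X0 <- matrix(0, ctx$n_c, 6, dimnames = list(NULL, st))
  for (s in 1:3) X0[, s] <- info$prevalence * ab$size_distribution[s]
  out <- run_cohorts_fast(dm$P, X0, ctx, cost, umult, trans_cost_row = tc_row,
                          disease_dead_col = which(st == "dead_aaa"))
  ## detections: screening detects everyone at t0; control presents at rupture
  if (arm == "screening") {
    out$diagnoses <- info$prevalence
  } else {
    out$diagnoses <- out$final[, "post_repair"] +
      out$final[, "dead_aaa"] # all control AAA deaths follow rupture
  }
  out
}

run_no_disease <- function(mass, ctx) {
  alive <- mass
  dq <- dly <- numeric(ctx$n_c)
  for (k in seq_len(ctx$N)) {
    nxt <- alive * (1 - ctx$Q[, k])
    mid <- (alive + nxt) / 2
    msk <- ctx$M[, k]
    dq <- dq + ctx$dfu[k] * mid * ctx$U[, k] * msk
    dly <- dly + ctx$dfu[k] * mid * msk
    alive <- nxt
  }
  list(cost = numeric(ctx$n_c), qaly = dq, ly = dly)
}

#' Evaluate the full model deterministically
#'
#' Runs the complete pipeline for a parameter set: screen-detectable
#' prevalence and stage distributions, the screening/diagnosis decision tree,
#' lifetime cohort Markov models for every modelled disease in both arms, and
#' aggregation into discounted per-person costs, life years, QALYs, the ICER,
#' the incremental net monetary benefit at the willingness-to-pay threshold,
#' its per-disease decomposition, and epidemiological outputs per 100,000
#' screened.
#'
#' @param params a validated parameter set.
#' @return an object of class `abdo_cea`; see [decompose_by_disease()] and
#'   [epi_outputs()] for its components.
#' @export
evaluate_model <- function(params) {
  ctx <- pipeline_context(params)
  coh <- ctx$cohorts
  wts <- coh$weight
  sched <- params$cost_schedule
  cn <- cost_negative_screen(sched)
  cp <- cost_positive_screen(sched)
  harm <- radiation_harm_decrement(params)
  sec_dec_unit <- params$settings$secondary_utility_decrement %||% 0
  wtp <- params$settings$wtp

  n_c <- ctx$n_c
  inc_cost_c <- rep(cn, n_c) + ctx$p_positive * (cp - cn) # screen cost, per cohort
  inc_qaly_c <- rep(-harm, n_c)
  inc_ly_c <- numeric(n_c)
  abs_cost_control <- numeric(n_c); abs_qaly_control <- numeric(n_c); abs_ly_control <- numeric(n_c)

  decomp <- list(); epi <- list()
  disease_rows <- function(organ, type, contrib) {
    data.frame(organ = organ, type = type, contribution = contrib)
  }

  for (nm in names(ctx$cancers)) {
    info <- ctx$cancers[[nm]]
    scr <- run_cancer_arm(info, params, ctx, "screening")
    ctl <- run_cancer_arm(info, params, ctx, "control")
    d_cost <- scr$cost - ctl$cost
    d_qaly <- scr$qaly - ctl$qaly
    d_ly <- scr$ly - ctl$ly
    diagc <- info$prevalence * (info$pathway_cost + (cp - cn)) # work-up + positive-screen delta
    inc_cost_c <- inc_cost_c + d_cost + info$prevalence * info$pathway_cost
    inc_qaly_c <- inc_qaly_c + d_qaly
    inc_ly_c <- inc_ly_c + d_ly
    abs_cost_control <- abs_cost_control + ctl$cost
    abs_qaly_control <- abs_qaly_control + ctl$qaly
    abs_ly_control <- abs_ly_control + ctl$ly
    decomp[[nm]] <- disease_rows(nm, "disease",
      sum(wts * (wtp * d_qaly - d_cost - diagc)))
    epi[[nm]] <- data.frame(
      disease = nm,
      deaths_prevented_per_100k = 1e5 * sum(wts * (ctl$disease_deaths - scr$disease_deaths)),
      additional_cases_per_100k = 1e5 * sum(wts * (scr$diagnoses - ctl$diagnoses)))
  }

  if (!is.null(ctx$aaa)) {
    info <- ctx$aaa
    scr <- run_aaa_arm(info, params, ctx, "screening")
    ctl <- run_aaa_arm(info, params, ctx, "control")
    d_cost <- scr$cost - ctl$cost; d_qaly <- scr$qaly - ctl$qaly; d_ly <- scr$ly - ctl$ly
    diagc <- info$prevalence * (info$pathway_cost + (cp - cn))
    inc_cost_c <- inc_cost_c + d_cost + info$prevalence * info$pathway_cost
    inc_qaly_c <- inc_qaly_c + d_qaly
    inc_ly_c <- inc_ly_c + d_ly
    abs_cost_control <- abs_cost_control + ctl$cost
    abs_qaly_control <- abs_qaly_control + ctl$qaly
    abs_ly_control <- abs_ly_control + ctl$ly
    decomp[[info$name]] <- disease_rows(info$name, "disease",
      sum(wts * (wtp * d_qaly - d_cost - diagc)))
    epi[[info$name]] <- data.frame(
      disease = info$name,
      deaths_prevented_per_100k = 1e5 * sum(wts * (ctl$disease_deaths - scr$disease_deaths)),
      additional_cases_per_100k = 1e5 * sum(wts * (scr$diagnoses - ctl$diagnoses)))
  }

  ## secondary findings: short-term diagnostic costs (and any scenario utility
  ## decrement), no long-term model
  if (length(ctx$secondary)) {
    for (i in seq_along(ctx$secondary)) {
      b <- ctx$secondary[[i]]
      minor <- b$category == "minor" # handled as a negative screen: no review,
                                     # no work-up, no disutility from follow-up
      delta <- if (minor) 0 else cp - cn
      dec <- if (minor) 0 else sec_dec_unit
      inc_cost_c <- inc_cost_c + b$prevalence * b$pathway_cost
      inc_qaly_c <- inc_qaly_c - dec * b$prevalence
      key <- paste0("secondary_", b$organ)
      contrib <- -sum(wts * b$prevalence * (b$pathway_cost + delta + wtp * dec))
      if (is.null(decomp[[key]])) {
        decomp[[key]] <- disease_rows(b$organ, "secondary", contrib)
      } else {
        decomp[[key]]$contribution <- decomp[[key]]$contribution + contrib
      }
    }
  }
  decomp[["no_disease"]] <- disease_rows("no_disease", "screening_only",
                                         -(cn + wtp * harm))

  nod <- run_no_disease(ctx$no_disease_mass, ctx)
  abs_qaly_control <- abs_qaly_control + nod$qaly
  abs_ly_control <- abs_ly_control + nod$ly

  inc <- list(cost = sum(wts * inc_cost_c), qaly = sum(wts * inc_qaly_c),
              ly = sum(wts * inc_ly_c))
  arms <- data.frame(
    arm = c("control", "screening"),
    cost = c(sum(wts * abs_cost_control), sum(wts * abs_cost_control) + inc$cost),
    qaly = c(sum(wts * abs_qaly_control), sum(wts * abs_qaly_control) + inc$qaly),
    ly = c(sum(wts * abs_ly_control), sum(wts * abs_ly_control) + inc$ly))

  decomposition <- do.call(rbind, decomp)
  rownames(decomposition) <- NULL
  total_inmb <- inmb(inc$cost, inc$qaly, wtp)
  if (abs(sum(decomposition$contribution) - total_inmb) > 1e-6) {
    stop("decomposition does not sum to total INMB", call. = FALSE)
  }

  cohort_results <- data.frame(
    start_age = coh$start_age, sex = coh$sex, weight = wts,
    inc_cost = inc_cost_c, inc_qaly = inc_qaly_c, inc_ly = inc_ly_c,
    inmb = wtp * inc_qaly_c - inc_cost_c)

  structure(list(
    arms = arms, incremental = inc,
    icer = icer(inc$cost, inc$qaly),
    inmb = total_inmb,
    wtp = wtp,
    decomposition = decomposition,
    epi = { e <- do.call(rbind, epi); rownames(e) <- NULL; e },
    cohort_results = cohort_results,
    p_positive = sum(wts * ctx$p_positive),
    mean_screen_cost = sum(wts * (cn + ctx$p_positive * (cp - cn)))
  ), class = "abdo_cea")
}

#' @export
print.abdo_cea <- function(x, ...) {
  cat("Incremental results per person screened:\n")
  cat(sprintf("  cost  GBP %8.2f\n  QALYs %10.5f\n  LYs   %10.5f\n",
              x$incremental$cost, x$incremental$qaly, x$incremental$ly))
  ic <- x$icer
  cat(sprintf("  ICER  %s\n", if (ic$code == "ratio") sprintf("GBP %0.0f/QALY", ic$value) else ic$code))
  cat(sprintf("  INMB  GBP %8.2f at GBP %0.0f/QALY\n", x$inmb, x$wtp))
  invisible(x)
}
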