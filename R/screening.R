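#' Screening cost per negative screen
#'
#' Sum of schedule items that apply to negative screens (reading/reporting and
#' the patient letter under the default schedule). The screening review
#' meeting and phone referral apply only to positive screens.
#'
#' @param schedule a screening cost schedule (`items` data.frame with
#'   `name`, `unit_cost`, `applies_to`; `review_meeting_batch`).
#' @return GBP per negative screen.
#' @export
cost_negative_screen <- function(schedule) {
  it <- schedule$items
  sum(it$unit_cost[it$applies_to %in% c("negative", "both")])
}

#' Screening cost per positive screen
#'
#' As [cost_negative_screen()] but including positive-only items; the
#' screening review meeting is an hourly cost shared across
#' `review_meeting_batch` scans, so it contributes `unit_cost / batch`.
#'
#' @inheritParams cost_negative_screen
#' @return GBP per positive screen.
#' @export
cost_positive_screen <- function(schedule) {
  it <- schedule$items
  keep <- it$applies_to %in% c("positive", "both")
  shared <- keep & grepl("review_meeting", it$name)
  sum(it$unit_cost[keep & !shared]) +
    sum(it$unit_cost[shared]) / schedule$review_meeting_batch
}

#' Expected screening cost per person screened
#'
#' Probability-weighted average of the negative and positive screen costs.
#'
#' @inheritParams cost_negative_screen
#' @param p_positive probability of a positive screen in \[0, 1\].
#' @return GBP per person screened.
#' @export
mean_screen_cost <- function(schedule, p_positive) {
  check_prob(p_positive, "p_positive")
  (1 - p_positive) * cost_negative_screen(schedule) +
    p_positive * cost_positive_screen(schedule)
}

#' Diagnostic work-up cost for a finding category
#'
#' Sum over the pathway's resources of unit cost times quantity. Minor
#' findings map to no pathway (`pathway_id = NULL`) under the roll-out
#' assumption that they are handled as negative screens, and cost 0.
#'
#' @param pathway_id pathway key, or `NULL` for no work-up.
#' @param pathways named list of pathway tables
#'   (`resource`, `unit_cost`, `quantity`).
#' @return GBP.
#' @export
diagnostic_cost <- function(pathway_id, pathways) {
  if (is.null(pathway_id)) return(0)
  pw <- pathways[[pathway_id]]
  if (is.null(pw)) stop(sprintf("no diagnostic pathway '%s'", pathway_id), call. = FALSE)
  sum(pw$unit_cost * pw$quantity)
}

#' One-off radiation-harm utility decrement per person screened
#'
#' The additional scan carries a small radiation-induced cancer risk,
#' represented as a one-off QALY decrement applied at screening in the
#' screening arm only, regardless of findings.
#'
#' @param params optional parameter set; its
#'   `settings$radiation_decrement` overrides the default 0.00078.
#' @return QALY decrement (positive number to be subtracted).
#' @export
radiation_harm_decrement <- function(params = NULL) {
  if (is.null(params)) 0.00078 else params$settings$radiation_decrement
}

#' Run the short-term screening and diagnosis decision tree for one cohort
#'
#' Derives the screen outcome distribution (cancers by organ and stage, AAA by
#' size, secondary findings by category, no finding), per-arm short-term costs
#' and utility decrements, and the initial Markov state masses. Both arms hold
#' the same underlying disease (disease missed by the screen is excluded from
#' both arms); the screening arm starts detected cases diagnosed at the
#' screen stage/size distribution, the control arm starts them undiagnosed at
#' the same distribution.
#'
#' @param params a validated parameter set.
#' @param cohort list or one-row data.frame with `start_age` and `sex`.
#' @return list with `p_positive`, `outcome_probs`, per-arm `short_term_cost`,
#'   `utility_decrement`, and `initial` masses per disease.
#' @export
run_decision_tree <- function(params, cohort) {
  age <- cohort$start_age
  sex <- cohort$sex
  sched <- params$cost_schedule
  mods <- params$modifiers

  cancers <- list(); aaa <- NULL
  for (nm in names(params$diseases)) {
    d <- params$diseases[[nm]]
    if (d$type == "cancer") {
      sd <- screen_detectable_prevalence(d, age, sex)
      w <- apply_stage_modifiers(sd$stage_distribution, d, mods)
      cancers[[nm]] <- list(prevalence = sd$prevalence, stage_distribution = w,
                            pathway_id = d$pathway_id)
    } else {
      prev <- age_sex_lookup(age_sex_matrix(d$prevalence), age, sex) *
        (d$prevalence_multiplier %||% 1)
      aaa <- list(name = nm, prevalence = prev,
                  size_distribution = d$size_distribution, pathway_id = d$pathway_id)
    }
  }

  sec <- lapply(params$secondary, function(b) {
    list(organ = b$organ, category = b$category,
         prevalence = age_sex_lookup(age_sex_matrix(b$prevalence), age, sex),
         pathway_id = b$pathway_id)
  })

  prev_cancer <- vapply(cancers, `[[`, numeric(1), "prevalence")
  prev_sec <- vapply(sec, `[[`, numeric(1), "prevalence")
  sec_positive <- vapply(sec, function(b) b$category != "minor", logical(1))
  total <- sum(prev_cancer) + (aaa$prevalence %||% 0) + sum(prev_sec)
  if (total > 1) { # mutually exclusive categories: renormalise overlapping prevalences
    scl <- 1 / total
    cancers <- lapply(cancers, function(x) { x$prevalence <- x$prevalence * scl; x })
    if (!is.null(aaa)) aaa$prevalence <- aaa$prevalence * scl
    sec <- lapply(sec, function(x) { x$prevalence <- x$prevalence * scl; x })
    prev_cancer <- prev_cancer * scl; prev_sec <- prev_sec * scl
    total <- 1
  }
  p_none <- 1 - total
  p_positive <- sum(prev_cancer) + (aaa$prevalence %||% 0) + sum(prev_sec[sec_positive])

  diag_cost <- sum(vapply(cancers, function(x) {
    x$prevalence * diagnostic_cost(x$pathway_id, params$pathways)
  }, numeric(1)))
  if (!is.null(aaa)) diag_cost <- diag_cost + aaa$prevalence * diagnostic_cost(aaa$pathway_id, params$pathways)
  diag_cost <- diag_cost + sum(vapply(sec, function(b) {
    if (b$category == "minor") 0 else b$prevalence * diagnostic_cost(b$pathway_id, params$pathways)
  }, numeric(1)))

  harm <- radiation_harm_decrement(params)
  sec_decrement <- (params$settings$secondary_utility_decrement %||% 0) *
    sum(prev_sec[sec_positive]) # minor findings are handled as negative screens

  outcome_probs <- c(prev_cancer,
                     if (!is.null(aaa)) stats::setNames(aaa$prevalence, aaa$name),
                     secondary = sum(prev_sec), none = p_none)

  list(
    p_positive = p_positive,
    outcome_probs = outcome_probs,
    screening = list(short_term_cost = mean_screen_cost(sched, p_positive) + diag_cost,
                     utility_decrement = harm + sec_decrement),
    control = list(short_term_cost = 0, utility_decrement = 0),
    initial = list(cancers = cancers, aaa = aaa, secondary = sec,
                   no_disease_mass = p_none + sum(prev_sec))
  )
}

## Scenario operators on the screen stage distribution:
## attenuation mixes the screen distribution toward the symptomatic
## (current) distribution; the stage-IV share multiplier rescales the late
## share and renormalises the early stages.
apply_stage_modifiers <- function(w, nh, mods) {
  if (any(is.na(w))) return(w)
  att <- mods$stage_shift_attenuation %||% 0
  if (att > 0) w <- (1 - att) * w + att * nh$current_stage_distribution
  s4 <- mods$stage4_share_multiplier %||% 1
  if (s4 != 1) {
    w4 <- min(w[4] * s4, 1)
    w[1:3] <- if (sum(w[1:3]) > 0) w[1:3] * (1 - w4) / sum(w[1:3]) else 0
    w[4] <- w4
  }
  w
}
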