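#' The pre-registered scenario catalogue
#'
#' Structural and parameter scenarios around the basecase: screening-arm
#' stage-specific mortality reductions (1a full effect, 1b half), stage-shift
#' operators (2a halved shift, 2b/2c late-stage share +/-25%), treatment-cost
#' multipliers (3a-3e), prevalence multipliers (4a-4d), a utility decrement
#' for secondary findings (5), the wider trial age range 55-81 (6), discount
#' rates of 1.5% and 5% (7a/7b) and disease-inclusion masks (8a no AAA,
#' 8b only AAA, 8c only kidney findings).
#'
#' @return named list of [scenario()] objects.
#' @export
scenario_catalogue <- function() {
  cancers <- CANCER_ORGANS
  list(
    "1a_mortality_reduction" = scenario("Reduced stage-specific mortality with screening",
      mortality_multiplier_screening = rep(0.75, 4)),
    "1b_mortality_reduction_half" = scenario("Reduced stage-specific mortality with screening (half impact)",
      mortality_multiplier_screening = rep(0.875, 4)),
    "2a_stage_shift_halved" = scenario("Cancer stage shifts with screening halved",
      stage_shift_attenuation = 0.5),
    "2b_stage4_plus25" = scenario("Stage IV share at screening 25% more",
      stage4_share_multiplier = 1.25),
    "2c_stage4_minus25" = scenario("Stage IV share at screening 25% less",
      stage4_share_multiplier = 0.75),
    "3a_metastatic_costs_halved" = scenario("Metastatic treatment costs halved",
      stage4_cost_multiplier = c(.all = 0.5)),
    "3b_metastatic_costs_halved_not_kidney" = scenario("Metastatic costs halved except kidney",
      stage4_cost_multiplier = stats::setNames(rep(0.5, 9), setdiff(cancers, "kidney"))),
    "3c_metastatic_costs_doubled" = scenario("Metastatic treatment costs doubled",
      stage4_cost_multiplier = c(.all = 2)),
    "3d_metastatic_costs_doubled_not_kidney" = scenario("Metastatic costs doubled except kidney",
      stage4_cost_multiplier = stats::setNames(rep(2, 9), setdiff(cancers, "kidney"))),
    "3e_all_costs_halved" = scenario("All cancer treatment costs halved",
      all_stage_cost_multiplier = c(.all = 0.5)),
    "4a_kidney_prevalence_doubled" = scenario("Kidney cancer prevalence doubled",
      prevalence_multiplier = c(kidney = 2)),
    "4b_kidney_prevalence_halved" = scenario("Kidney cancer prevalence halved",
      prevalence_multiplier = c(kidney = 0.5)),
    "4c_all_prevalence_doubled" = scenario("All cancer prevalence doubled",
      prevalence_multiplier = c(.all = 2)),
    "4d_all_prevalence_halved" = scenario("All cancer prevalence halved",
      prevalence_multiplier = c(.all = 0.5)),
    "5_secondary_utility_decrement" = scenario("Utility decrement for secondary findings",
      secondary_utility_decrement = 0.005),
    "6_trial_age_range" = scenario("Trial population age distribution (55-81)",
      age_range = c(55, 81)),
    "7a_discount_1.5" = scenario("Discount rates 1.5%", discount_rate = 0.015),
    "7b_discount_5" = scenario("Discount rates 5%", discount_rate = 0.05),
    "8a_no_aaa" = scenario("No AAA findings included",
      include_organs = cancers),
    "8b_only_aaa" = scenario("Only AAA findings included",
      include_organs = "aaa"),
    "8c_only_kidney" = scenario("Only kidney findings included",
      include_organs = "kidney")
  )
}

#' Run the scenario grid
#'
#' Applies each scenario to the base parameter set and evaluates it
#' (deterministically for `n = 1`, probabilistically otherwise), returning a
#' grid of incremental results with the basecase as the first row.
#'
#' @param params base parameter set.
#' @param catalogue named list of scenarios (default [scenario_catalogue()]).
#' @param n probabilistic runs per scenario (1 = deterministic).
#' @param seed integer seed for probabilistic runs.
#' @return data.frame: scenario id/name, incremental cost/LY/QALY, INMB,
#'   ICER value and code, and probability cost-effective (`NA` when n = 1).
#' @export
run_scenarios <- function(params, catalogue = scenario_catalogue(), n = 1,
                          seed = NULL) {
  seed <- seed %||% params$settings$rng_seed
  entries <- c(list(basecase = NULL), catalogue)
  rows <- lapply(names(entries), function(id) {
    scn <- entries[[id]]
    p <- if (is.null(scn)) params else apply_scenario(params, scn)
    cea <- evaluate_model(p)
    prob <- NA_real_
    if (n > 1) {
      prob <- run_psa(p, n = n, seed = seed)$prob_cost_effective
    }
    data.frame(id = id,
               name = if (is.null(scn)) "Basecase" else scn$name,
               inc_cost = cea$incremental$cost,
               inc_ly = cea$incremental$ly,
               inc_qaly = cea$incremental$qaly,
               inmb = cea$inmb,
               icer = cea$icer$value,
               icer_code = cea$icer$code,
               prob_cost_effective = prob)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
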