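test_that("sojourn-to-probability bridge matches its closed form and limits", {
  expect_equal(sojourn_to_annual_probability(1), 1 - exp(-1))
  expect_equal(sojourn_to_annual_probability(2), 1 - exp(-0.5))
  expect_lt(sojourn_to_annual_probability(1e9), 1e-8) # no progression limit
  expect_error(sojourn_to_annual_probability(0))
  expect_error(sojourn_to_annual_probability(-2))
})

test_that("single-stage toy prevalence equals incidence x sojourn x sensitivity", {
  # all detectable sojourn in stage I with (almost) no outflow to diagnosis
  nh <- toy_cancer_block(dwell = c(5, 1e6, 1e6, 1e6),
                         stage_dist = c(1 - 3e-9, 1e-9, 1e-9, 1e-9),
                         sens = c(0.8, 0, 0, 0), coverage = 1,
                         incidence = 1e-4)
  # with a (1,0,0,0)-like target the calibrated stage-I diagnosis probability
  # approaches 1... use instead a no-diagnosis variant: tiny stage-I share is
  # impossible, so construct directly via the kernel with zero diagnosis
  kern <- screen_detect_kernel(nh, d = c(0, 0, 0, 1 - exp(-1e-6)))
  expect_equal(1e-4 * kern$per_stage_kernel[1], 4e-4, tolerance = 1e-6)
})

test_that("zero sensitivity gives zero prevalence with a flagged stage distribution", {
  nh <- toy_cancer_block(sens = c(0, 0, 0, 0))
  out <- screen_detectable_prevalence(nh, 60, "male")
  expect_equal(out$prevalence, 0)
  expect_true(out$degenerate)
  expect_true(all(is.na(out$stage_distribution)))
})

test_that("prevalence is monotone in sensitivity, coverage and dwell time", {
  base <- toy_cancer_block()
  p0 <- screen_detectable_prevalence(base, 62, "female")$prevalence
  up_sens <- base; up_sens$sensitivity <- pmin(base$sensitivity + 0.05, 1)
  up_cov <- base; up_cov$coverage <- 0.5
  expect_gt(screen_detectable_prevalence(up_sens, 62, "female")$prevalence, p0)
  expect_lt(screen_detectable_prevalence(up_cov, 62, "female")$prevalence, p0)
  up_dwell <- base; up_dwell$dwell_time <- base$dwell_time * 1.5
  expect_gt(screen_detectable_prevalence(up_dwell, 62, "female")$prevalence, p0)
})

test_that("longer late-stage dwell shifts the screen stage distribution late", {
  early <- toy_cancer_block(dwell = c(4, 2, 1, 0.8))
  late <- toy_cancer_block(dwell = c(4, 2, 3, 2.5))
  w_early <- screen_detectable_prevalence(early, 60, "male")$stage_distribution
  w_late <- screen_detectable_prevalence(late, 60, "male")$stage_distribution
  expect_gt(sum(w_late[3:4]), sum(w_early[3:4]))
  # microsimulation agrees on the direction
  ms_early <- microsim_prevalence(early, 60, "male", n = 2e5, seed = 3)
  ms_late <- microsim_prevalence(late, 60, "male", n = 2e5, seed = 3)
  expect_gt(ms_late$prevalence, ms_early$prevalence)
})

test_that("analytic prevalence agrees with the microsimulation oracle", {
  nh <- toy_cancer_block()
  analytic <- screen_detectable_prevalence(nh, 60, "male")$prevalence
  ms <- microsim_prevalence(nh, 60, "male", n = 3e5, seed = 11)
  expect_lt(abs(analytic - ms$prevalence), 3 * ms$se)
})

test_that("calibration reproduces boundary and interior targets", {
  # near-boundary target: (almost) everyone diagnosed in stage I
  nh1 <- toy_cancer_block(stage_dist = c(1 - 3e-7, 1e-7, 1e-7, 1e-7))
  d1 <- calibrate_diagnosis_rates(nh1)
  achieved1 <- forward_stage_at_diagnosis(
    sojourn_to_annual_probability(nh1$dwell_time), d1)
  expect_lt(max(abs(achieved1 - nh1$current_stage_distribution)), 1e-6)
  expect_gt(d1[1], 0.99)

  # two-stage toy with equal dwell times and a (0.5, 0.5)-style target
  nh2 <- toy_cancer_block(dwell = c(2, 2, 2, 2),
                          stage_dist = c(0.5, 0.5 - 2e-9, 1e-9, 1e-9))
  d2 <- calibrate_diagnosis_rates(nh2)
  achieved2 <- forward_stage_at_diagnosis(
    sojourn_to_annual_probability(nh2$dwell_time), d2)
  expect_lt(max(abs(achieved2 - nh2$current_stage_distribution)), 1e-6)

  # self-consistency on the tuned kidney block
  kid <- default_params()$diseases$kidney
  dk <- calibrate_diagnosis_rates(kid)
  achk <- forward_stage_at_diagnosis(sojourn_to_annual_probability(kid$dwell_time), dk)
  expect_lt(max(abs(achk - kid$current_stage_distribution)), 1e-6)
})
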