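test_that("the default bundle holds the eleven modelled diseases and validates", {
  p <- default_params()
  expect_s3_class(p, "abdo_params")
  expect_length(p$diseases, 11)
  types <- vapply(p$diseases, `[[`, character(1), "type")
  expect_equal(sum(types == "cancer"), 10)
  expect_equal(sum(types == "aaa"), 1)
})

test_that("validation rejects out-of-range probabilities and negative costs", {
  p <- default_params()
  bad <- p
  bad$diseases$kidney$sensitivity[2] <- 1.4
  expect_error(validate_parameter_set(bad), "diseases.kidney.sensitivity")

  bad <- p
  bad$treatment_cost[3, 1] <- -10
  expect_error(validate_parameter_set(bad), "treatment_cost")

  bad <- p
  bad$cohorts$weight[1] <- bad$cohorts$weight[1] + 0.01
  expect_error(validate_parameter_set(bad), "sum to 1")

  bad <- p
  bad$diseases$kidney$current_stage_distribution <- c(0.5, 0.3, 0.1, 0.2)
  expect_error(validate_parameter_set(bad), "current_stage_distribution")

  bad <- p
  bad$diseases$kidney$pathway_id <- "nonexistent"
  expect_error(validate_parameter_set(bad), "nonexistent")
})

test_that("write-then-load round-trips the parameter set field-wise", {
  p <- default_params()
  dir <- withr::local_tempdir()
  write_parameter_set(p, dir)
  expect_error(write_parameter_set(p, dir), "already holds")
  q <- load_parameter_set(dir)
  expect_equal(unclass(q)[order(names(q))], unclass(p)[order(names(p))],
               tolerance = 1e-12, ignore_attr = TRUE)
  # and loading must be usable: same deterministic evaluation
  expect_equal(evaluate_model(q)$inmb, evaluate_model(p)$inmb, tolerance = 1e-9)
})

test_that("apply_scenario is pure and targets exactly what it names", {
  p <- toy_params()
  p_before <- p

  doubled <- apply_scenario(p, scenario("2x kidney", prevalence_multiplier = c(kidney = 2)))
  expect_equal(doubled$diseases$kidney$prevalence_multiplier, 2)
  expect_identical(p, p_before) # base untouched
  # everything else bit-identical
  d2 <- doubled; d2$diseases$kidney$prevalence_multiplier <- 1
  expect_identical(unclass(d2), unclass(p_before))
  # and the derived screen-detectable prevalence doubles exactly
  s1 <- screen_detectable_prevalence(p$diseases$kidney, 60, "male")
  s2 <- screen_detectable_prevalence(doubled$diseases$kidney, 60, "male")
  expect_equal(s2$prevalence, 2 * s1$prevalence)

  ident <- apply_scenario(p, scenario("identity"))
  expect_identical(unclass(ident), unclass(p))

  disc <- apply_scenario(p, scenario("1.5%", discount_rate = 0.015))
  expect_equal(disc$settings$discount_rate_costs, 0.015)
  expect_equal(disc$settings$discount_rate_qalys, 0.015)

  expect_error(apply_scenario(p, scenario("bad", prevalence_multiplier = c(spleen = 2))),
               "spleen")
  expect_error(apply_scenario(p, scenario("bad", unknown_knob = 1)), "unknown_knob")
})

test_that("PSA draws are seed-reproducible, respect fixed values and simplexes", {
  p <- toy_params()
  a <- sample_psa_draws(p, 4, seed = 42)
  b <- sample_psa_draws(p, 4, seed = 42)
  expect_identical(a, b)
  c <- sample_psa_draws(p, 4, seed = 43)
  expect_false(identical(a, c))

  for (dr in a) {
    expect_equal(sum(dr$diseases$kidney$current_stage_distribution), 1, tolerance = 1e-12)
    expect_s3_class(validate_parameter_set(dr), "abdo_params")
    # parameters without a distribution keep their fixed value
    expect_identical(dr$cost_schedule, p$cost_schedule)
  }

  all_fixed <- p
  all_fixed$psa_distributions <- list(
    "settings.radiation_decrement" = distribution("fixed", value = 0.00078))
  d <- sample_psa_draws(all_fixed, 3, seed = 7)
  for (dr in d) expect_identical(unclass(dr), unclass(all_fixed))
})

test_that("beta draws match analytic moments and kind/target mismatches error", {
  p <- toy_params()
  p$psa_distributions <- list(
    "diseases.kidney.sensitivity.1" = distribution("beta", alpha = 2, beta = 2))
  set.seed(1)
  vals <- replicate(10000, draw_parameter_set(p)$theta[[1]])
  se <- sqrt(1 / (4 * (2 + 2 + 1)) / 10000) # var of beta(2,2) = 1/20
  expect_lt(abs(mean(vals) - 0.5), 3 * se)

  bad <- p
  bad$psa_distributions <- list(
    "diseases.aaa.elective_repair.cost" = distribution("beta", alpha = 2, beta = 2))
  expect_error(sample_psa_draws(bad, 1, seed = 1), "non-probability")
  expect_error(sample_psa_draws(
    { b <- p; b$psa_distributions <- list("diseases.nope.dwell_time.1" =
        distribution("fixed", value = 1)); b }, 1, seed = 1), "unknown parameter path")
})

test_that("distribution parameter invariants are enforced", {
  expect_error(distribution("beta", alpha = -1, beta = 2), "invalid parameters")
  expect_error(distribution("gamma", shape = 1, scale = 0), "invalid parameters")
  expect_error(distribution("lognormal", meanlog = 0, sdlog = 0), "invalid parameters")
  expect_error(distribution("dirichlet", alpha = c(1, 0)), "invalid parameters")
  expect_error(distribution("weibull", shape = 1), "unknown distribution kind")
})
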