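test_that("screen cost components reproduce the itemised schedule", {
  sched <- default_cost_schedule()
  expect_equal(cost_negative_screen(sched), 21.85)
  expect_equal(round(cost_positive_screen(sched), 2), 39.39)

  empty <- list(items = data.frame(name = character(0), unit = character(0),
                                   unit_cost = numeric(0), applies_to = character(0)),
                review_meeting_batch = 15)
  expect_equal(cost_negative_screen(empty), 0)
  expect_equal(cost_positive_screen(empty), 0)

  free_reading <- sched
  free_reading$items$unit_cost[free_reading$items$name == "radiologist_reading"] <- 0
  expect_equal(cost_negative_screen(free_reading), 6.85)

  batch1 <- sched; batch1$review_meeting_batch <- 1
  expect_equal(cost_positive_screen(batch1), 242.57)
  batch_huge <- sched; batch_huge$review_meeting_batch <- 1e12
  expect_equal(cost_positive_screen(batch_huge), 24.88, tolerance = 1e-9)
})

test_that("mean screen cost is the linear blend of the endpoint costs", {
  sched <- default_cost_schedule()
  cn <- cost_negative_screen(sched); cp <- cost_positive_screen(sched)
  expect_equal(mean_screen_cost(sched, 0), cn)
  expect_equal(mean_screen_cost(sched, 1), cp)
  p_implied <- (26.77 - 21.85) / (39.39 - 21.85)
  expect_equal(round(mean_screen_cost(sched, p_implied), 2), 26.77)
  for (p in c(0.1, 0.5, 0.9)) {
    v <- mean_screen_cost(sched, p)
    expect_gte(v, cn); expect_lte(v, cp)
    expect_equal(v, cn + p * (cp - cn))
  }
  expect_error(mean_screen_cost(sched, 1.2), "p_positive")
})

test_that("diagnostic costs sum resource use; minor findings cost nothing", {
  pathways <- list(
    toy = data.frame(resource = c("ct", "clinic"), unit_cost = c(120, 150),
                     quantity = c(1, 2)),
    empty = data.frame(resource = character(0), unit_cost = numeric(0),
                       quantity = numeric(0)))
  expect_equal(diagnostic_cost("toy", pathways), 420)
  expect_equal(diagnostic_cost("empty", pathways), 0)
  expect_equal(diagnostic_cost(NULL, pathways), 0) # minor finding, roll-out assumption
  expect_error(diagnostic_cost("missing", pathways), "missing")
})

test_that("radiation harm is a one-off 0.00078 decrement with scenario override", {
  expect_equal(radiation_harm_decrement(), 0.00078)
  p <- toy_params()
  expect_equal(radiation_harm_decrement(p), 0.00078)
  p2 <- apply_scenario(p, scenario("no harm", radiation_decrement = 0))
  expect_equal(radiation_harm_decrement(p2), 0)
})

test_that("decision tree: harm-only limit when no disease is detectable", {
  p <- toy_params()
  for (nm in names(p$diseases)) {
    if (p$diseases[[nm]]$type == "cancer") p$diseases[[nm]]$sensitivity <- rep(0, 4)
    else p$diseases[[nm]]$prevalence$value <- 0
  }
  p$secondary <- list()
  dt <- run_decision_tree(p, list(start_age = 60, sex = "male"))
  expect_equal(dt$p_positive, 0)
  expect_equal(dt$screening$short_term_cost, cost_negative_screen(p$cost_schedule))
  expect_equal(dt$control$short_term_cost, 0)
  expect_equal(dt$screening$utility_decrement, 0.00078)
  # whole-model check: incremental QALYs = -0.00078, applied undiscounted at t0
  cea <- evaluate_model(p)
  expect_equal(cea$incremental$qaly, -0.00078)
  expect_equal(cea$incremental$cost, cost_negative_screen(p$cost_schedule))
})

test_that("decision tree branch probabilities are coherent across arms", {
  p <- default_params()
  dt <- run_decision_tree(p, list(start_age = 65, sex = "female"))
  expect_equal(sum(dt$outcome_probs), 1, tolerance = 1e-9)
  expect_true(all(dt$outcome_probs >= 0))
  expect_gte(dt$screening$short_term_cost, 0)
  # screening-arm initial diagnosed stage distribution equals the screen
  # stage distribution from the natural-history module (pass-through)
  kid <- screen_detectable_prevalence(p$diseases$kidney, 65, "female")
  expect_equal(dt$initial$cancers$kidney$stage_distribution, kid$stage_distribution)
  expect_equal(dt$initial$cancers$kidney$prevalence, kid$prevalence)
  # both arms carry the same underlying disease mass
  expect_equal(dt$initial$no_disease_mass +
                 sum(vapply(dt$initial$cancers, `[[`, numeric(1), "prevalence")) +
                 dt$initial$aaa$prevalence, 1, tolerance = 1e-9)
})

test_that("negative screens never cost more than positive screens", {
  sched <- default_cost_schedule()
  expect_lte(cost_negative_screen(sched), cost_positive_screen(sched))
  set.seed(4)
  for (i in 1:20) {
    it <- data.frame(name = paste0("item", 1:5), unit = "u",
                     unit_cost = stats::runif(5, 0, 100),
                     applies_to = sample(c("negative", "positive", "both"), 5, TRUE))
    it$applies_to[1] <- "both"
    s <- list(items = it, review_meeting_batch = sample(1:20, 1))
    neg_only <- sum(it$unit_cost[it$applies_to == "negative"])
    if (neg_only == 0) expect_lte(cost_negative_screen(s), cost_positive_screen(s) + 1e-12)
  }
})
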