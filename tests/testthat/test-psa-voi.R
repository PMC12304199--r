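test_that("all-fixed distributions collapse the PSA onto the deterministic run", {
  p <- toy_params()
  p$psa_distributions <- list(
    "settings.radiation_decrement" = distribution("fixed", value = 0.00078))
  det <- evaluate_model(p)
  ps <- run_psa(p, n = 4, seed = 123)
  expect_equal(ps$rejected, 0L)
  expect_true(all(abs(ps$draws$inmb - det$inmb) < 1e-12))
  expect_equal(ps$prob_cost_effective, as.numeric(det$inmb > 0))
})

test_that("PSA is seed-reproducible with stored draws and sampled values", {
  p <- toy_params()
  a <- run_psa(p, n = 6, seed = 31)
  b <- run_psa(p, n = 6, seed = 31)
  expect_identical(a$draws, b$draws)
  expect_identical(a$theta, b$theta)
  expect_equal(nrow(a$draws), 6)
  expect_equal(ncol(a$theta), length(unlist(lapply(
    p$psa_distributions, function(d) if (d$kind == "dirichlet") d$params$alpha else 1))))
  c <- run_psa(p, n = 6, seed = 32)
  expect_false(identical(a$draws, c$draws))
})

test_that("CEAC follows its definition at the limits and the threshold", {
  ps <- psa_toy(inc_cost = c(-5, 10, 20, -1), inc_qaly = c(0.001, -0.002, 0.004, 0.0001))
  cc <- ceac(ps, c(0, 20000, 1e9))
  expect_equal(cc$prob_cost_effective[1], mean(ps$draws$inc_cost < 0))
  expect_equal(cc$prob_cost_effective[3], mean(ps$draws$inc_qaly > 0))
  expect_equal(cc$prob_cost_effective[cc$wtp == 20000], ps$prob_cost_effective)
  degenerate <- psa_toy(rep(10, 5), rep(0.01, 5))
  expect_equal(ceac(degenerate, 20000)$prob_cost_effective, 1)
})

test_that("EVPI equals 5 on the enumerable two-strategy toy and is never negative", {
  nb <- cbind(a = c(0, 0), b = c(10, -10))
  expect_equal(evpi(nb), 5) # mean(max) = 5, max(mean) = 0
  dominant <- cbind(a = c(1, 2, 3), b = c(0, 1, 2))
  expect_equal(evpi(dominant), 0)
  set.seed(17)
  for (i in 1:25) {
    nbr <- matrix(stats::rnorm(40), 20, 2)
    expect_gte(evpi(nbr), -1e-12)
  }
})

test_that("percentile intervals match analytic quantiles on a normal toy", {
  set.seed(5)
  q <- stats::rnorm(20000, mean = 0.005, sd = 0.001)
  ps <- psa_toy(inc_cost = rep(50, 20000), inc_qaly = q)
  lims <- stats::quantile(ps$draws$inmb, c(0.025, 0.975), names = FALSE)
  analytic <- 20000 * (0.005 + c(-1, 1) * 1.959964 * 0.001) - 50
  expect_equal(lims, analytic, tolerance = 0.02)
})

test_that("EVPPI: independence gives ~0, deterministic dependence gives ~EVPI", {
  set.seed(8)
  n <- 2000
  x <- stats::runif(n); z <- stats::runif(n)
  nb_screen <- 40 * sin(2 * pi * x) + 5 # deterministic in x
  ps <- psa_toy(inc_cost = -nb_screen, inc_qaly = rep(0, n))
  ps$theta <- cbind(driver.x = x, noise.z = z)
  total <- evpi(psa_net_benefit(ps))
  dep <- evppi(ps, "driver.x")
  ind <- evppi(ps, "noise.z")
  expect_lt(abs(dep$evppi - total), 0.05 * total)
  expect_lt(ind$evppi, 0.05 * total + 0.01)
  expect_gte(dep$evppi, 0)
  expect_lte(dep$evppi, total * 1.05 + 0.01)
  expect_error(evppi(ps, "nonexistent."), "matches no sampled")
})

test_that("grouped EVPPI on the model PSA respects the EVPI bound", {
  p <- toy_params()
  ps <- run_psa(p, n = 200, seed = 77)
  total <- evpi(psa_net_benefit(ps))
  expect_gte(total, 0)
  g <- evppi(ps, "diseases.kidney.dwell_time")
  expect_gte(g$evppi, 0)
  expect_lte(g$evppi, total * 1.05 + 0.01)
  expect_match(g$method, "gam")
})

test_that("scenario grid includes the basecase and the full catalogue", {
  p <- toy_params()
  cat2 <- scenario_catalogue()[c("7a_discount_1.5", "7b_discount_5")]
  grid <- run_scenarios(p, cat2, n = 1)
  expect_equal(nrow(grid), 3)
  expect_equal(grid$id[1], "basecase")
  expect_gt(grid$inmb[grid$id == "7a_discount_1.5"],
            grid$inmb[grid$id == "7b_discount_5"])
  expect_equal(nrow(run_scenarios(p, list(), n = 1)), 1)
  expect_length(scenario_catalogue(), 21)
})
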