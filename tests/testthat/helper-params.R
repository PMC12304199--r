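# Shared fixtures, built in code. The tuned default set is generated once per
# test session; the toy set keeps one cancer and the AAA block on a narrow age
# window for fast engine-level checks.

default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_default_parameters()
    cache
  }
})

toy_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- apply_scenario(default_params(),
                          scenario("toy", include_organs = c("kidney", "aaa"),
                                   age_range = c(60, 62)))
      p$secondary <- list()
      cache <<- validate_parameter_set(p)
    }
    cache
  }
})

# a minimal hand-built cancer block for natural-history tests
toy_cancer_block <- function(dwell = c(4, 2, 1.5, 1),
                             stage_dist = c(0.4, 0.3, 0.2, 0.1),
                             sens = c(0.8, 0.85, 0.9, 0.9),
                             coverage = 1,
                             mortality = c(0.02, 0.05, 0.15, 0.45),
                             incidence = 1e-4) {
  ages <- 55:100
  list(type = "cancer", organ = "toy",
       incidence = do.call(rbind, lapply(c("male", "female"), function(sx) {
         data.frame(age = ages, sex = sx, value = incidence)
       })),
       dwell_time = dwell, current_stage_distribution = stage_dist,
       sensitivity = sens, coverage = coverage, cancer_mortality = mortality,
       prevalence_multiplier = 1, cost_multiplier = rep(1, 4))
}
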