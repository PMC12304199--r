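#!/usr/bin/env Rscript

# Scenario grid: structural and parameter uncertainty around the basecase
# (stage shift, screening mortality effect, treatment costs, prevalence,
# secondary-finding disutility, age range, discounting, disease inclusion).

suppressMessages(library(abdoscreen))

params <- load_parameter_set("results/params")
out_dir <- "results/scenarios"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

grid <- run_scenarios(params, scenario_catalogue(), n = 1)
utils::write.csv(grid, file.path(out_dir, "scenario_grid.csv"), row.names = FALSE)
write_run_manifest(out_dir, command = "04_scenarios", params_path = "results/params",
                   seed = params$settings$rng_seed,
                   scenarios = names(scenario_catalogue()))

print(grid[, c("id", "inc_cost", "inc_qaly", "inmb", "icer_code")], digits = 4)
base_inmb <- grid$inmb[grid$id == "basecase"]
cat(sprintf("\nBasecase INMB GBP %.2f.\n", base_inmb))
cat("Removing AAA flips the result:",
    sprintf("INMB GBP %.2f without AAA, GBP %.2f with only AAA.\n",
            grid$inmb[grid$id == "8a_no_aaa"], grid$inmb[grid$id == "8b_only_aaa"]))
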