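#!/usr/bin/env Rscript

# Value of information: per-person EVPI from the probabilistic runs, and
# grouped EVPPI (regression-based conditional-expectation estimator) for the
# parameter families most relevant to trial design: cancer dwell times,
# AAA parameters, scan sensitivity and stage-specific cancer mortality.

suppressMessages(library(abdoscreen))

params <- load_parameter_set("results/params")
out_dir <- "results/voi"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- params$settings$rng_seed

psa <- run_psa(params, n = params$settings$n_psa, seed = seed)
total <- evpi(psa_net_benefit(psa))

cancers <- names(Filter(function(d) d$type == "cancer", params$diseases))
groups <- list(
  cancer_dwell_times = paste0("diseases.", cancers, ".dwell_time"),
  aaa_parameters = "diseases.aaa.",
  scan_sensitivity = paste0("diseases.", cancers, ".sensitivity"),
  cancer_mortality = paste0("diseases.", cancers, ".cancer_mortality"),
  prevalence = paste0("diseases.", cancers, ".prevalence_multiplier"),
  treatment_costs = "treatment_cost."
)
rows <- lapply(names(groups), function(nm) {
  est <- evppi(psa, groups[[nm]])
  data.frame(group = nm, evppi_gbp = est$evppi, method = est$method,
             edf = est$edf)
})
voi <- do.call(rbind, rows)
voi <- voi[order(-voi$evppi_gbp), ]

utils::write.csv(data.frame(measure = "evpi_per_person_gbp", value = total),
                 file.path(out_dir, "evpi.csv"), row.names = FALSE)
utils::write.csv(voi, file.path(out_dir, "evppi_by_group.csv"), row.names = FALSE)
write_run_manifest(out_dir, command = "05_voi", params_path = "results/params",
                   seed = seed, n_psa = psa$n)

cat(sprintf("EVPI: GBP %.3f per person\n", total))
cat("Grouped EVPPI (GBP per person):\n")
print(voi, digits = 3, row.names = FALSE)
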