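#!/usr/bin/env Rscript

# Build the default (study-like) parameter bundle and write it to disk.
# The generator self-calibrates disease incidence to the published detection
# yield per 4019 scanned and the secondary-finding mix to the implied
# positive-screen rate; everything downstream loads this bundle.

suppressMessages(library(abdoscreen))

out_dir <- "results/params"
seed <- 1L

params <- generate_default_parameters(synthetic_config(seed = seed))
write_parameter_set(params, out_dir, force = TRUE)
write_run_manifest("results", command = "01_generate_parameters",
                   params_path = out_dir, seed = seed)

counts <- validate_against_counts(
  { p <- params; p$age_range <- c(55, 81); p }, scale = 4019)
cat("Expected screen-detected counts per 4019 scanned (55-81):\n")
print(counts, digits = 3)
cat(sprintf("\nKidney %.1f, other cancers %.1f, AAA %.1f\n",
            counts$expected[counts$disease == "kidney"],
            sum(counts$expected[!counts$disease %in% c("kidney", "aaa")]),
            counts$expected[counts$disease == "aaa"]))
cat(sprintf("Parameter bundle written to %s\n", out_dir))
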