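#!/usr/bin/env Rscript

# Probabilistic sensitivity analysis: 2000 runs propagating the parameter
# distributions through the whole pipeline; exports the CE plane, the
# cost-effectiveness acceptability curve and credible intervals.

suppressMessages(library(abdoscreen))

params <- load_parameter_set("results/params")
out_dir <- "results/psa"
seed <- params$settings$rng_seed

psa <- run_psa(params, n = params$settings$n_psa, seed = seed)
cea <- evaluate_model(params)
export_cea_tables(cea, out_dir, psa = psa)
write_run_manifest(out_dir, command = "03_psa", params_path = "results/params",
                   seed = seed, n_psa = psa$n)

cat(sprintf("PSA with %d runs (seed %d, %d rejected draws)\n",
            psa$n, psa$seed, psa$rejected))
cat(sprintf("Mean incremental cost GBP %.2f [%.2f, %.2f]\n",
            psa$means[["inc_cost"]], psa$ci[1, "inc_cost"], psa$ci[2, "inc_cost"]))
cat(sprintf("Mean incremental QALYs %.5f [%.5f, %.5f]\n",
            psa$means[["inc_qaly"]], psa$ci[1, "inc_qaly"], psa$ci[2, "inc_qaly"]))
cat(sprintf("Mean INMB GBP %.2f [%.2f, %.2f]\n",
            psa$means[["inmb"]], psa$ci[1, "inmb"], psa$ci[2, "inmb"]))
cat(sprintf("Probability cost-effective at GBP %d/QALY: %.3f\n",
            params$settings$wtp, psa$prob_cost_effective))
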