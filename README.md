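# abdoscreen

Health-economic modelling of a one-off upper abdominal CT screen offered as
an add-on to thoracic CT lung cancer screening. People eligible for lung
screening (heavy smoking history, ages 55–74) are at elevated risk of kidney
and other abdominal cancers and of abdominal aortic aneurysm (AAA); the same
scanner visit can screen for all of them at small incremental cost. This
package is for health-economic modellers and screening researchers who want
to reproduce, stress or extend that evaluation.

## The model

A decision tree captures the short-term screening episode: the itemised
incremental cost of reading and reporting the extra scan (£21.85 per negative
screen; £39.39 per positive screen, including a 1/15 share of an hourly review
meeting), diagnostic work-up pathways for each finding, and a one-off
radiation-harm utility decrement of 0.00078 per person screened. Long-term
consequences accrue in lifetime annual-cycle cohort Markov models, one per
modelled condition (ten cancers, AAA, and a no-disease model), run separately
for each age/sex cohort and reassembled by weighting.

For each cancer, screen-detectable prevalence and the stage distribution at
screening are derived from incidence, per-stage mean sojourn ("dwell") times,
scan sensitivity and organ coverage by a length-biased closed form

    prevalence_s = entry_s · sojourn_s · sensitivity_s · coverage ,

and control-arm symptomatic presentation rates are calibrated by root finding
so the model reproduces the observed stage-at-diagnosis distribution. Cancer
states are undiagnosed/diagnosed × stage I–IV (diagnosed states split by time
since diagnosis), with stage-specific annual mortality, treatment costs and
utility multipliers; the screening arm starts diagnosed at the screen stage
distribution, the control arm undiagnosed at the same distribution. The AAA
model tracks aneurysm size (surveillance and elective repair when detected;
growth, rupture and emergency repair when not). Outputs are discounted
(3.5%/yr) incremental costs, life years and QALYs per person screened, the
ICER, the incremental net monetary benefit (INMB = λ·ΔQALY − ΔCost at
λ = £20,000/QALY) with a per-disease decomposition, deaths prevented per
100,000 screened, probabilistic sensitivity analysis (2000 runs), a scenario
grid, and expected value of (partial) perfect information.

The study's full parameter file is not public, so the bundled generator
produces a synthetic parameter set tuned to the published anchors (detection
yield per 4019 scanned, the screening cost schedule, the implied
positive-screen rate) at realistic natural-history magnitudes; see the
methods vignette (`vignettes/model-methods.Rmd`) for exactly what it does and
does not emulate.

## Worked example

```r
library(abdoscreen)
params <- generate_default_parameters()   # tuned synthetic parameter set
cea <- evaluate_model(params)             # deterministic basecase
cea
#> Incremental results per person screened:
#>   cost  GBP    88.94
#>   QALYs    0.00627
#>   LYs      0.00919
#>   ICER  GBP 14191/QALY
#>   INMB  GBP    36.41 at GBP 20000/QALY
```

Screening costs £88.94 extra per person over their lifetime and gains
0.00627 QALYs, i.e. £14,191 per QALY — cost-effective at the £20,000/QALY
threshold, with a net benefit of £36.41 per person screened. The
decomposition shows where that comes from:

```r
d <- decompose_by_disease(cea)
head(d[order(-d$contribution), ], 4)
#>                  organ    type contribution
#> 11                 aaa disease    74.123902
#> 1               kidney disease    49.669953
#> 7                colon disease    12.114093
#> 6  upper_urinary_tract disease     5.992489
```

AAA detection is the largest contributor, then kidney cancer; pancreatic,
liver, gallbladder cancer and lymphomas contribute negatively, and every
secondary-finding category costs money for no modelled benefit (kidney
secondary findings alone −£40.36). Dropping AAA from the model
(`apply_scenario(params, scenario_catalogue()[["8a_no_aaa"]])`) flips the
result to INMB −£37.72: multi-disease accounting is what makes the screen
cost-effective. Epidemiologically the model predicts about 205 deaths from
modelled diseases prevented per 100,000 screened, 169 of them from AAA
(`epi_outputs(cea)`).

The numbered scripts under `analysis/` run the full study sequence —
`01_generate_parameters.R` (write the parameter bundle),
`02_basecase.R`, `03_psa.R` (2000 probabilistic runs, CE plane, CEAC),
`04_scenarios.R` (21-scenario grid), `05_voi.R` (EVPI and grouped EVPPI) —
each writing CSV tables and a reproducibility manifest under `results/`.

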