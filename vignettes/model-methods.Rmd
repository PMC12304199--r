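---
title: "Model methods: multi-disease economics of an add-on upper abdominal CT screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: multi-disease economics of an add-on upper abdominal CT screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the model evaluates

People attending low-dose thoracic CT for lung cancer screening can receive a
one-off upper abdominal scan in the same visit at small incremental cost. The
scan can detect kidney and other abdominal cancers before symptoms, abdominal
aortic aneurysms (AAA), and many incidental ("secondary") findings. This
package estimates the lifetime incremental costs, life years and
quality-adjusted life years (QALYs) of adding that scan, per person screened,
from a health-service perspective.

The structure is a short-term decision tree feeding lifetime cohort Markov
models with annual cycles. Age (55-81) and sex cohorts are modelled separately
and reassembled by weighting, with the basecase restricted to the
lung-screening-eligible window 55-74. Two arms are compared. Both arms harbour
the same underlying disease: a case detectable at screening enters the
screening arm *diagnosed* at its screen-detected stage (or under AAA
surveillance at its detected size) and enters the control arm *undiagnosed* at
the same stage, progressing until symptomatic presentation. Disease missed by
the scan, pre-existing diagnosed disease, and disease arising after the screen
are excluded from both arms, so every modelled difference is attributable to
the screen itself.

## Screen-detectable prevalence

For each cancer the preclinical natural history is a progressive four-stage
model entered at stage I at the age/sex incidence rate. Each stage has a mean
sojourn (dwell) time; constant within-stage hazards map dwell times to annual
probabilities via `1 - exp(-1/dwell)`. Undiagnosed disease can also present
symptomatically; those per-stage presentation probabilities are *calibrated*
(see below). Cross-sectional (length-biased) reasoning then gives the
probability a screened person harbours detectable stage-s disease:

    prevalence_s = entry_rate_s x effective_sojourn_s x sensitivity_s x coverage

where the effective sojourn is `1/(progression rate + presentation rate)`
(stage IV competes with cancer death instead of progression), and the entry
rate into stage s+1 is the entry rate into stage s times the probability of
progressing before presentation. Competing other-cause mortality is ignored
inside this closed form — it is second-order at sojourns of a few years — but
is applied fully in the cohort models; a million-individual Monte-Carlo
microsimulation oracle in the test suite confirms the closed form within
Monte-Carlo error. The stage distribution at screening is the normalised
per-stage vector, which is what produces the stage shift: longer early-stage
sojourns concentrate detectable prevalence in early stages.

AAA and secondary-finding prevalence are direct age/sex inputs (in a trial
they are observed, not derived).

## Calibration of symptomatic presentation

Control-arm cases must reproduce the observed stage-at-diagnosis distribution.
Within a cycle, presentation (probability `d_s`) pre-empts progression, so an
entrant into stage s is eventually diagnosed there with probability
`d_s / (d_s + (1-d_s) p_s)`. The package solves stages I-III sequentially by
bracketed root finding (`stats::uniroot`) so each stage's unconditional share
of diagnoses matches its target. The stage-IV presentation probability is not
identified by the stage distribution (conservation fixes the stage-IV share
once stages I-III match), so it is taken from the stage-IV dwell time, read as
the mean preclinical time to symptomatic presentation. The calibration chain
conditions on surviving other causes; in the full model, other-cause death
truncates late diagnoses, which is why screening can *increase* lifetime
diagnoses — it finds cases in people who would otherwise have died of other
causes first. Calibration is verified to reproduce its target within 1e-6
(sup-norm) by an independent forward cohort simulation.

## Markov models and rewards

Cancer models have 14 states: undiagnosed stages I-IV; diagnosed stages I-IV
split into first-year and subsequent-year states (treatment costs and utility
multipliers differ by time since diagnosis); death from the cancer; death from
other causes. Undiagnosed states carry baseline utility and no treatment cost
— the benefit of screening flows entirely through earlier diagnosis. Diagnosed
states carry stage- and phase-specific treatment costs and utility multipliers
applied to age/sex baseline utility. Diagnosed disease does not progress
between stages; stage at diagnosis governs mortality, following the
stage-specific-survival logic of staged cancer models. Undiagnosed stage IV
dies at the diagnosed stage-IV rate (late-stage disease kills whether or not
formally diagnosed); undiagnosed stages I-III carry no cancer mortality.

The AAA model has three sizes (3.0-4.4, 4.5-5.4, >= 5.5 cm), post-repair and
two death states. Detected aneurysms are under surveillance (annual cost by
size) and electively repaired on reaching the large state (operative
mortality; one-off cost charged whether or not the operation is survived).
Undetected aneurysms grow and rupture at size-specific annual probabilities;
rupture triggers emergency repair with a survival probability (cost charged
for survivors, many deaths occurring before surgery). The no-disease model is
alive/dead with age-specific utilities.

Other-cause mortality composes multiplicatively: with probability `q(age)` an
alive state moves to death from other causes; otherwise the within-disease
transition applies. This keeps every row stochastic by construction; the
additive competing risks inside the disease transitions are checked for
overflow. Rewards use a trapezoidal half-cycle correction (mean of start- and
end-cycle occupancy) and completed cycle k is discounted by `(1+r)^-k`, 3.5%
per year for costs and QALYs in the basecase. The engine is verified against
the fundamental-matrix closed form `(I - dQ)^-1` on random time-homogeneous
chains to 1e-10. The horizon is age 100, by which point all-cause mortality
in this heavy-smoking population has absorbed nearly all occupancy.

The multi-cohort production path propagates all age/sex cohorts as a single
occupancy block per disease and arm (the within-disease matrix is
age-invariant; only other-cause survival varies by cohort-cycle), which is
what makes 2000-run probabilistic analyses take minutes; it is tested for
exact agreement with the per-cohort engine.

## The decision tree and short-term quantities

The itemised screening cost schedule distinguishes negative screens (reading
plus result letter, GBP 21.85) from positive screens (additionally a share of
the screening review meeting — an hourly cost split across 15 scans — and a
phone referral, GBP 39.39). Minor findings are costed as negative screens on
the assumption that routine roll-out would not review them. Each positive
finding incurs its diagnostic work-up pathway cost at time zero. Radiation
from the extra scan carries a one-off utility decrement of 0.00078 per person
screened, applied in the screening arm regardless of findings. Finding
categories are treated as mutually exclusive (no patient carries two modelled
diseases), renormalising in the synthetic extreme where prevalences overlap.

## Economic outputs

Per-person incremental cost, life years and QALYs are cohort-weighted;
the ICER carries dominance codes; the incremental net monetary benefit (INMB)
is `WTP x dQALY - dCost` at GBP 20,000/QALY. The INMB decomposition gives
each organ its Markov-phase net benefit plus its diagnostic work-up and
positive-screen cost delta; secondary findings contribute their short-term
costs (and scenario disutility); the "no disease" row carries the universal
negative-screen base cost and the radiation harm. Rows sum to the total INMB
by construction and this identity is asserted at 1e-6 on every evaluation.
Because per-screen cost passes one-for-one into incremental cost, the maximum
justifiable screen cost is simply the current mean screen cost plus the INMB;
the full-model round trip of that identity is part of the acceptance tests.
Epidemiological outputs (deaths prevented, additional diagnoses, per 100,000
screened) come from cumulative occupancy of the disease-death states and
cumulative diagnosis flows.

## Probabilistic and scenario analysis

Probabilities carry beta distributions, costs gamma, dwell times and
prevalence multipliers lognormal, and stage/size simplexes dirichlet (the
simplex is preserved by construction rather than renormalised). Draws are
independent across parameters — no correlation structure is asserted — except
where a dirichlet ties a simplex together. Each of the 2000 runs re-executes
the entire pipeline, including recalibration of presentation probabilities.
Draws are seed-indexed (a fixed offset sequence), so any run is reproducible
in isolation; invalid draws are rejected and redrawn with an incremented
sub-seed, keeping the run count fixed.

The scenario catalogue covers: screening-arm stage-specific mortality
multipliers (defaults 0.75 and 0.875 — the external evidence the study cites
for this effect is not reproducible here, so these are package defaults, and
they are exposed as a user-suppliable vector); halving the stage shift
(implemented by mixing the screen stage distribution halfway toward the
symptomatic distribution — the halving operator is not otherwise defined, so
this choice is documented and switchable); +/-25% on the stage-IV share at
screening; treatment-cost and prevalence multipliers; a one-off utility
decrement of 0.005 per reviewed secondary finding (applied to serious and
false-positive categories, not to minor findings handled as negative
screens); the wider 55-81 trial age range; 1.5%/5% discounting; and
disease-inclusion masks (no AAA, only AAA, only kidney findings).

Value of information: EVPI is the mean-of-best minus best-of-mean net
benefit over the two strategies. Grouped EVPPI uses the regression approach:
each strategy's net benefit is smoothed on the group's sampled values with
thin-plate-spline GAMs (`mgcv`, smoothness by GCV); groups larger than four
parameters are first projected onto four principal components. Estimator
metadata (method, effective degrees of freedom, run count) is always
reported, and the estimator is exercised in the tests at its exact
(enumerable), independence (EVPPI about 0) and deterministic-dependence
(EVPPI about EVPI) limits.

## The synthetic parameter set

The study's full parameter file is not public, so the bundled generator
emulates its structure and published anchors rather than its values:

* expected detection yield per 4019 scanned of about 10 kidney cancers, 10
  other cancers combined, 60 AAA and several hundred serious or
  follow-up-requiring secondary findings — per-disease incidence levels are
  solved in closed form against these targets;
* the exact itemised screening cost schedule;
* an overall positive-screen rate of about 0.28, back-solved from the
  published weighted-average screen cost of GBP 26.77 against the GBP
  21.85/39.39 endpoints, with false-positive secondary prevalences scaled to
  close the residual;
* natural-history, survival, cost and utility magnitudes chosen at values a
  modeller in this field would recognise: steep stage gradients in survival
  for kidney, colon, stomach and urinary-tract cancer; poor prognosis at all
  stages for pancreas, liver and gallbladder; late-concentrated detectable
  sojourn for lymphoma (nodal disease visible on CT is typically already
  disseminated); kidney-concentrated secondary findings (stones, complex
  cysts); one treatment-cost schedule shared by all cancers, as the study
  assumes;
* a Gompertz-shaped life table scaled on the hazard scale by a smoking
  hazard ratio of 2, and EQ-5D-like age-declining baseline utilities.

The generated set reproduces the qualitative result pattern: positive INMB
driven mainly by AAA, then kidney cancer; negative contributions from
pancreas, liver, lymphoma, gallbladder and every secondary-finding category;
loss of cost-effectiveness when AAA is excluded or only kidney findings are
modelled; and declining cost-effectiveness with age. It does **not** claim to
reproduce the study's supplementary values, and headline magnitudes (INMB,
ICER, deaths prevented) should be read as order-of-magnitude emulations, not
replications. Two known divergences: the wider 55-81 population remains
marginally cost-effective here (the study found it not to be), because the
synthetic age gradients keep AAA benefit positive into the late 70s; and the
probability cost-effective is lower than the study's 0.96 because the
synthetic uncertainty widths are conventions, not fitted posteriors.

## Numerical choices and degenerate inputs

* Calibration tolerance 1e-6 (sup-norm), root bracketing on (1e-14, 1-1e-14),
  boundary targets clamped; infeasible targets raise an error naming the
  stage.
* Zero total detectable prevalence returns prevalence 0 with a flagged,
  undefined stage distribution (and zero mass downstream) rather than NaN.
* Row-stochasticity (1e-9), occupancy conservation (1e-9) and the
  decomposition identity (1e-6) are asserted at run time, not assumed.
* Cohort weights renormalise within the configured age window; weights are
  validated to sum to 1 at 1e-9.
* Problem sizes used by the checks: 100 random chains for the engine oracle,
  50 random blocks for calibration recovery, 10 instances x 1e6 individuals
  for the prevalence microsimulation, and the full 2000-run PSA for the
  probabilistic properties.

## Limitations

One-off screen only (no repeat rounds); diseases modelled independently (no
multimorbidity, a small double-counting risk the study also accepts);
diagnosed cancers do not progress between stages; secondary findings carry no
long-term consequences; no uptake modelling (attenders only); no
societal-perspective costs. The pre-existing national AAA screening offer to
65-year-old men is not modelled, so the study's sharp male age-65/66
discontinuity does not appear here.
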