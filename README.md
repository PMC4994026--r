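# microdcm

Dynamic causal modelling (DCM) of stimulus-evoked, source-level EEG with a
canonical-microcircuit (CMC) neural-mass model — as one reusable, tested R
package.

## Who this is for

Researchers who want to ask *where exogenous drive enters a cortical
network* and *how effective connectivity changes with experimental
condition*, given per-subject evoked time series ("virtual electrodes") for
two conditions.  The motivating application is an 8-source object-naming
network (bilateral early visual cortex, anterior ventral temporal cortex,
angular gyrus, inferior frontal gyrus) under repetition priming, with three
competing input architectures:

1. input to visual cortex only (a traditional bottom-up hierarchy — family 1);
2. input to visual *and* frontal cortex (family 2);
3. input to visual cortex plus a direct feedforward visual→frontal edge
   (family 2).

## The model in brief

Each source holds four neural populations (spiny stellate, superficial
pyramidal, inhibitory interneurons, deep pyramidal), each governed by a
second-order synaptic kernel

    dv/dt = i,    di/dt = κ a(t) − 2κ i − κ² v,    κ = 1/τ,

coupled through a centred sigmoid firing function S(v) = 1/(1+e^{−rv}) − ½.
Forward connections run sp → (ss, dp) of the target, backward connections
dp → (sp, ii), every extrinsic edge with a conduction delay D (ms); a
Gaussian bump u(t) scaled by per-source gains C drives the granular layer.
Condition effects multiply connection strengths and superficial-pyramidal
gain by exp(B).  Inversion is variational Laplace (Gauss–Newton ascent on
the free energy F = accuracy − complexity); group inference is
random-effects Bayesian model selection with exceedance probabilities, and
family-level inference with a size-calibrated prior.  Subjects fitting below
0.75 variance explained are re-initialized at the mean posterior of the
well-fitting subjects and refitted.

Since no EEG recordings ship with the package, a first-class synthetic
module generates ground-truth cohorts (older-like: model 2, slower forward
conduction, repetition effects on visual→temporal forward strength, faster
naming with stronger frontal input; younger-like: model 3, repetition effect
on temporal-lobe gain) so the whole pipeline is testable end to end.

## Worked example

```r
library(microdcm)

old <- generate_cohort(cohort_spec("older",   n_subjects = 3, hemispheres = "left", seed = 11))
yng <- generate_cohort(cohort_spec("younger", n_subjects = 3, hemispheres = "left", seed = 12))
report <- run_study(study_manifest(list(older = old, younger = yng), n_samples = 1e5),
                    progress = FALSE)
print(report)
```

On this miniature study (3 subjects per group, reduced 4-source network)
the run printed:

```
study_report
  older: winning family 2, winning model 2 (median fit 0.962)
    family exceedance: 1=0.062 2=0.938
    within-family exceedance: 2=0.937 3=0.063
  younger: winning family 2, winning model 3 (median fit 0.961)
    family exceedance: 1=0.062 2=0.938
    within-family exceedance: 2=0.062 3=0.938
  forward-delay contrast: 8.26 vs 8.00 ms (t = 0.71, p = 0.535)
```

Reading it: both groups' inversions fit well (~0.96 variance explained);
the older-like cohort is correctly assigned to family 2 with model 2 (dual
visual+frontal input) winning within the family, the younger-like cohort to
model 3 (visual input with a direct visual→frontal shortcut); the
forward-delay contrast (generative truth: 9.18 vs 7.98 ms) has the right
sign but is not significant at n = 3 — at the tested cohort sizes (n = 15)
the full suite measures this property across seeds.  `report$groups` also
carries per-subject evidence tables, harvested parameters (input gains C,
condition-resolved modulations B, gains G, delays D in ms), repetition-effect
t-tests and the input-strength/reaction-time correlation.

Behavioural arithmetic is exact where the source numbers are exact, e.g.
`priming_effect(815.9, 727.0)` returns `88.9` (ms).

## Command line

```sh
Rscript inst/cli/microdcm.R model build --id 3 --out model3.json
Rscript inst/cli/microdcm.R simulate --group older --n 15 --seed 7 --out cohort_old/
Rscript inst/cli/microdcm.R invert --data cohort_old/o01 --model model3.json
Rscript inst/cli/microdcm.R compare --evidence evidence_older.tsv --families "1:1;2:2,3"
Rscript inst/cli/microdcm.R pipeline --older cohort_old/ --younger cohort_young/ --out report/
```

## Package layout

- `R/neural_dynamics.R` — CMC parameters, sigmoid, stimulus, grid, integrator wrapper
- `src/cmc_integrate.cpp` — fixed-step RK4 delayed-network integrator
- `R/model_space.R` — the three architectures, modulations, families, JSON I/O
- `R/observation.R` — LFP readout and variance-explained fit score
- `R/inversion.R` — parameter packing, variational Laplace, re-initialization
- `R/bms.R` — random-effects and family-level BMS, exceedance probabilities
- `R/synthetic_data.R` — ground-truth cohort generator (ERPs + behaviour)
- `R/analysis_pipeline.R` — harvesting, statistics, `run_study()`
- `vignettes/microdcm-methods.Rmd` — model, assumptions, defaults, limitations
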