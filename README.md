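# lymphpbpk

Population whole-body PBPK simulation of subcutaneous macromolecule
absorption with lymphatic uptake.

Large molecules injected subcutaneously do not simply diffuse into blood:
they are swept by convection into lymphatic capillaries and transit the
lymphatic network before reaching the circulation. Predicting their plasma
concentration–time course in a *population* therefore needs two things that
standard population-PBPK generators omit: interindividual variability in the
lymphatic system itself, and a mechanistic description of local drainage
from the injection depot. lymphpbpk provides both, built around a ~45 kDa
pegylated peptide as the reference compound, for modelers and clinical
pharmacologists planning or analyzing first-in-human studies of
subcutaneously dosed macromolecules.

## What the package implements

**Virtual-population generator.** Adult males built from a sampled height
and seventeen compartment masses (15 tissues + blood + lymph), each drawn
from a normal or log-normal distribution re-centered allometrically —
tissues by height, blood and lymph by body weight, skin by body surface area
(Gehan–George, BSA = 0.0235 W^0.515 H^0.422), all with a 3/4-power rule:

    M = M_ref (H / H_ref)^(3/4)

Draws are truncated to the central 95 % and floored at one tenth of the
mean; body weight is the exact sum of parts; blood splits 2/3 venous, 1/3
arterial. Blood flows come from fixed reference perfusion, lymph flow is
0.2 % of organ blood flow (0.1 % for skin), GFR = renal plasma flow ×
filtration fraction, and accepted individuals satisfy weight 60–80 kg and
GFR 90–150 mL/min.

**Whole-body PBPK model.** Venous/arterial plasma, a lymph node, and
vascular + interstitial spaces of 15 organs, with lung in series and the
splanchnic organs draining through the liver. Convective transport with
vascular (σ_v, globally scaled by σ_sf) and lymphatic (σ_i) reflection
coefficients. The SC dose enters a skin depot whose volume equals the
injected volume; the depot drains into a **lymphatic drainage compartment
(LDC)** sized as a fraction of the injection volume,

    V_LDC = Vfrac × V_injection ,

which delays early transit into the lymph node — the feature that removes
the early-time over-prediction of depot→node models. Renal clearance is
0.1 % of GFR; non-renal clearance scales from a reference primate by body
weight. The system is linear; its rate matrix conserves mass by
construction and is integrated stiffly with a mass-balance check at every
output time.

**Around the core:** non-compartmental analysis (linear-up/log-down),
pooled and two-stage estimation of Vfrac from concentration–time data, a
synthetic first-in-human trial emulator (5 SC cohorts 45–720 mg, 20
subjects, LOQ 1 µg/mL), one-at-a-time mean and eleven-scenario distribution
sensitivity analyses, YAML configuration with full validation, and a thin
CLI (`inst/cli/lymphpbpk.R`).

## Worked example

```r
library(lymphpbpk)

# 1. Generate and qualify a 1000-subject virtual population
pop <- generate_population(1000, seed = 1)
summary(pop)
#>   variable    mean    sd     cv   min   max
#> 1 weight_kg   70.8  5.01 0.0708  60.0  80.0
#> 2 height_cm  177.   7.20 0.0406 155.  200.
#> 3 bmi_kg_m2   22.6  2.08 0.0918  16.9  32.1
#> 4 gfr_ml_min 122.  16.1  0.132   90.6 150.
autoplot(pop)   # weight/height/BMI/GFR histograms

# 2. Simulate the reference male at the lowest trial dose and summarize
ref <- reference_individual()
sim <- simulate_pbpk(build_pbpk_model(ref, drug_params(),
                                      dose_event(45, 100)),
                     times = c(seq(0.5, 48, 0.5), seq(50, 1050, 5)))
nca(plasma_profile(sim))
#>    cmax  tmax lambda_z auc_last auc_inf t_half
#> 1  4.94   135  0.00387    2006.   2056.   179.
```

A 45 mg dose peaks at about 4.9 µg/mL around 135 h — absorption is rate-
limited by skin lymph flow and the LDC transit — and declines with a
terminal half-life near 180 h, about one third of the exposure being
cleared renally.

```r
# 3. Emulate the trial and recover the drainage volume fraction
trial <- generate_trial(seed = 1)          # truth: per-subject Vfrac ~ 0.25
fit <- fit_vfrac(trial, mode = "two_stage", weighting = "combined")
fit
#> Vfrac fit (two_stage mode)
#>   estimate: 0.2382  between-subject CV: 59.6%
#>   objective (variance-weighted residual sum of squares): 293.9632
#>   20 subjects, 226 observations
```

The recovered mean (0.238 here) sits within sampling error of the
generating value 0.25; `tidy()` and `glance()` return the same results as
tibbles.

## Configuration and CLI

All physiologic and drug constants live in one validated YAML document
(`inst/extdata/default_config.yaml`); unknown keys and invariant violations
are rejected with messages naming every offending field. The CLI wraps the
package functions:

```sh
Rscript inst/cli/lymphpbpk.R generate-population --n 1000 --seed 1 --out pop
Rscript inst/cli/lymphpbpk.R make-trial --seed 1 --out obs
Rscript inst/cli/lymphpbpk.R fit-vfrac --data obs.csv --mode two_stage \
        --weighting combined --out fit
Rscript inst/cli/lymphpbpk.R sensitivity --mode distribution --seed 1 --out bands
```

Every run writes a JSON manifest with the command, config digest, seed and
output list.

See `vignettes/model-and-methods.Rmd` for the model equations, assumptions,
estimator properties and known limitations.
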