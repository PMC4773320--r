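---
title: "Model and methods: population PBPK of subcutaneous lymphatic uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: population PBPK of subcutaneous lymphatic uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

lymphpbpk simulates the plasma time course of a large, slowly cleared
macromolecule — the reference case is a ~45 kDa pegylated peptide — after
subcutaneous (SC) injection in a virtual population of healthy adult males.
Macromolecules do not diffuse freely across capillary walls; they reach the
circulation largely by convection into lymphatic capillaries and transit
through the lymphatic network. The package therefore couples a whole-body
physiologically based pharmacokinetic (PBPK) model with an anthropometric
population generator that treats the lymphatic system as a first-class,
variable compartment, and with a lymphatic drainage compartment (LDC) that
delays transit from the injection depot into the lymph node.

This vignette is the package's own account of the model, its assumptions,
the tunable parameters and the numerical choices. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## The virtual-population generator

Each individual is built from a sampled body height (normal, default mean
178 cm, CV 4 %, configurable — representative of non-obese adult males) and
seventeen compartment masses: fifteen tissues plus blood and lymph. Every
compartment mass is drawn from a normal or log-normal distribution whose mean
is a fixed percentage of the 71 kg reference male's body weight, re-centered
to the individual by allometric scaling:

* tissues scale with height: $M = M_\mathrm{ref}\,(H/H_\mathrm{ref})^{3/4}$;
* blood and lymph scale with body weight through the same 3/4 power —
  vessel volume grows with body size, and lymph variability is set equal to
  blood variability (CV 22 %, log-normal), treating the lymphatics as a
  parallel circulatory tree;
* skin scales linearly with body surface area (Gehan–George,
  $\mathrm{BSA} = 0.0235\,W^{0.515}H^{0.422}$).

Weight-based re-centering is circular if "body weight" means the final sum of
parts, so the generator uses a provisional weight derived from the reference
BMI, $W_\mathrm{prov} = 24\,(H/100)^2$ kg, to drive the weight and BSA rules;
the individual's body weight is then defined as the exact sum of all sampled
compartment masses. Blood is partitioned 2/3 venous, 1/3 arterial.

Two safeguards keep normal draws physiologic: sampling is symmetrically
truncated to the central 95 % of each distribution (implemented by inverse-CDF
sampling on U(0.025, 0.975), which is draw-for-draw equivalent to rejecting
and redrawing beyond the 2.5th/97.5th percentiles but deterministic), and the
result is floored at one tenth of the re-centered mean. Log-normal
distributions are parameterized so the *arithmetic* mean and CV match their
targets, since the input table reports means. Truncation leaves a normal mean
unchanged and shifts a log-normal mean down slightly (about 3.5 % at the
largest CV used, 56 %); the test suite bounds this shift.

Hematocrit (mean 0.42, CV 2 %) and the renal filtration fraction (mean 0.20,
CV 2.94 %) default to log-normal — the narrative convention — with a config
switch to normal; at these CVs the two are numerically indistinguishable.

Organ blood flows use fixed reference perfusion: reference cardiac output
(5.6 L/min) times the organ's flow fraction, divided by the reference organ
mass, then multiplied by the individual's sampled mass. Plasma flow is blood
flow times $(1-\mathrm{hct})$. Lymph flow is a fixed fraction of blood flow:
0.2 % for every organ except skin, which uses 0.1 %. GFR is renal plasma flow
times the filtration fraction. Candidates are accepted only if body weight
lies in 60–80 kg and GFR in 90–150 mL/min, the enrolment window of the
emulated first-in-human study; rejected candidates are resampled. Per-organ
flow fractions, cardiac output, and the organ volume fractions below are not
part of the published parameter table; they ship as editable,
literature-typical defaults in `inst/extdata/default_config.yaml`.

## The whole-body model

The system tracks amounts (µg) in venous and arterial plasma, a lymph-node
compartment, and vascular plus interstitial sub-compartments of 15 organs
(volumes from organ mass at unit density; vascular plasma space
$F_{vv} V (1-\mathrm{hct})$, interstitium $F_{vic} V$). Lung sits in series
on total plasma flow; spleen, pancreas and the intestines drain through the
liver vascular space. Transcapillary transport is convective with reflection
coefficients: filtrate $L_i$ crosses the vascular wall carrying solute flux
$L_i(1-\sigma_{sf}\sigma_{v,i})C_{vas}$, and lymph drains the interstitium at
$L_i(1-\sigma_i)C_{int}$ into the lymph node, which returns to venous plasma.
A single scaling factor $\sigma_{sf}$ multiplies every organ's vascular
reflection coefficient; validation refuses any effective value outside
[0, 1].

The skin interstitium is split into an injection depot, whose volume equals
the injected volume (dose/concentration, 0.45–4.8 mL across the emulated
cohorts), and the residual interstitial space. The depot drains only
lymphatically — it has no direct vascular exchange — into the LDC at
$Q_{dep}(1-\sigma_i)C_{dep}$ with
$Q_{dep} = L_{skin} V_{dep}/V_{int,skin}$: the skin lymph flow is
partitioned between depot and residual space in proportion to volume, the
minimal assumption consistent with injected material spreading through the
interstitium (a `depot_drainage_mode = "full"` switch reproduces the older
convention in which the depot drained at the entire skin lymph flow). The LDC
is a flow-through transit volume, $V_{LDC} = V_{frac} \times V_{dep}$,
emptying into the lymph node at the same volumetric rate it fills; no sieving
occurs within lymphatics. A useful consequence of this parameterization is
that the depot emptying rate constant is independent of injection volume,
while the LDC transit time is $V_{frac} V_{int,skin}/L_{skin}$ — so
$V_{frac}$ directly controls the early-time delay that distinguishes the
model from its LDC-free predecessor.

Clearances: renal clearance is $F_{GFR} \times$ GFR (default 0.1 % of GFR)
acting on kidney vascular plasma; non-renal clearance is scaled from a 3.4 kg
reference primate by the body-weight ratio (exponent configurable, default 1)
and apportioned over venous and arterial plasma plus all interstitial spaces
by relative volume. The primate value (1.9 mL/h) was chosen so that the
renally cleared share of a dose in the reference male is approximately one
third, matching the compound's reported clearance composition; it is a config
entry, not a fitted quantity.

Because the system is linear with constant coefficients, the model is
assembled as an explicit transfer-rate matrix in which every flow appears
once as an outflux and once as an influx (clearances flow into bookkeeping
states). All column sums are therefore zero and total mass is conserved by
construction; the build step asserts this, and the integration step checks
that the mass-balance residual stays below $10^{-6}$ of dose at every output
time. Integration uses `deSolve::lsoda` with the analytic constant Jacobian,
absolute tolerance $10^{-10}$ µg and relative tolerance $10^{-8}$. The test
suite verifies the integrator against a hand-derived Bateman transit chain
and against a matrix-exponential solution of the full system, both to
$10^{-6}$ relative.

Units are µg, mL, mL/h and h throughout; doses in mg are converted on entry.
Dose linearity is exact (no saturable terms exist), which the tests exploit.

## Non-compartmental analysis

`nca()` uses the linear-up/log-down trapezoid, the standard PK convention;
$\lambda_z$ comes from a log-linear regression on the last five positive
concentrations (count configurable, reported in the output), AUC is
extrapolated as $C_{last}/\lambda_z$, and ties at Cmax resolve to the
earliest time. The published analysis does not state its trapezoid variant or
terminal window; these defaults are flagged in the result metadata.

## Estimating the drainage volume fraction

$V_{frac}$ is fitted to dose-normalized concentration–time data using the
mean (reference) human for prediction and each subject's actual injected
volume, with below-limit observations excluded and a deterministic bounded
search on (0, 2] from three starts. Two modes and two residual weightings are
provided:

* **pooled** — one $V_{frac}$ minimizing summed residuals over all subjects;
* **two_stage** — per-subject fits whose mean and CV are reported;
* weighting `"log"` — squared log-concentration residuals (constant-CV
  error); `"combined"` — linear-scale residuals weighted by
  $1/(\sigma_{prop}^2 \hat C^2 + \sigma_{add}^2)$, the extended-least-squares
  weighting for a combined proportional-plus-additive assay error.

These replace the original analysis's commercial nonlinear mixed-effects
estimator (FOCE-ELS) with documented, dependency-free procedures. The choice
among them matters. On synthetic trials with the default study conditions
(between-subject $V_{frac}$ CV 68 %, 15 % proportional + 0.5 µg/mL additive
error, 1 µg/mL LOQ), the pooled log-residual fit systematically
underestimates the generating mean, for three reasons the test data make
visible: excluding below-limit points preferentially removes the early
samples of slow-absorbing (high-$V_{frac}$) subjects; log residuals are
mis-specified where the additive error dominates, just above the LOQ; and a
mean-model fit to data pooled across a strongly heterogeneous population is
biased toward small $V_{frac}$ by the convexity of the
concentration–$V_{frac}$ map. The two-stage estimator with combined weighting
is free of the pooling bias and is the package's recommended route to the
population mean; the acceptance pipeline uses it, and the acceptance test
requires the mean of five replicate recoveries to fall within 10 % of the
generating value. The pooled log-residual mode is retained as specified, is
exact on noise-free data (a test asserts recovery within 1 %), and its
objective is reported for model discrimination. The two-stage between-subject
CV is a simple empirical CV of per-subject estimates; it is reported but not
claimed equivalent to a mixed-effects variability estimate, and no standard
error comparable to an NLME precision is produced.

Model discrimination uses the median-deviation objective: the average over
cohorts and nominal times of the absolute difference between median predicted
and median observed concentrations. The tests verify the directional claim
that including the LDC reduces this objective and that omitting the LDC
uniformly over-predicts plasma concentrations in the first ten hours. The
absolute objective values reported for the original clinical dataset depend
on proprietary observations and are not reproduced.

## The synthetic trial

`generate_trial()` emulates the first-in-human single-ascending-dose design:
five cohorts of four subjects (45, 90, 180, 360, 720 mg; only the extreme
doses and the total of 20 subjects are fixed by the study description — the
intermediate levels are declared assumptions, configurable), injected
concentrations of 100–150 mg/mL so no single injection exceeds 2 mL (the
depot holds the summed volume), nominal sampling from 0.5 h to 1050 h, and a
combined 15 % proportional + 0.5 µg/mL additive residual error with
censoring below the 1 µg/mL limit of quantitation. Per-subject $V_{frac}$ is
drawn from a truncated, floored normal distribution (mean 0.25, CV 68 %;
log-normal available by config — with truncation the two give similar
predictions). The generator returns a truth table for recovery testing.

What the emulation does *not* contain limits what passing tests show about
real data: there is no model misspecification (data are generated by the same
structural model that is fitted), no anomalous-injection subjects, no
dropout or dosing-time deviations, and the residual error is exactly the
error model the estimator assumes when `weighting = "combined"`. Recovery
results therefore demonstrate internal consistency of the estimation
machinery, not clinical identifiability.

## Sensitivity analyses

The mean one-at-a-time analysis perturbs $V_{frac}$, $\sigma_{sf}$,
$\sigma_i$, non-renal clearance, skin lymph-flow fraction and $F_{GFR}$ by
±10 % ($\sigma_{sf}$ upward only +1 %, so no organ's effective reflection
coefficient can exceed 1), simulates 100 individuals at the lowest dose
(45 mg), and reports the percent change in AUC, Cmax and Tmax of the
pointwise-median profile. The distribution analysis runs eleven scenarios
(halved/doubled $V_{frac}$ CV; 10 %/50 % CVs added to the skin lymph-flow
fraction and to $\sigma_i$; blood-, lymph- or skin-mass distributions
removed; 20 % CV added to $F_{GFR}$) over 1000 individuals each and reports
pointwise median and 5th–95th percentile bands. Both use a paired
common-random-numbers design — the same seed, hence closely matched
individuals, under every scenario — to isolate parameter effects; the
original report does not state pairing, and an unpaired design would only
add Monte-Carlo noise to the contrasts. Percent changes are computed on NCA
metrics of the median profile, not medians of per-individual metrics. Added
per-individual distributions on the skin lymph-flow fraction, $\sigma_i$ and
$F_{GFR}$ are log-normal (these are positive fractions; $\sigma_i$ draws are
additionally capped at 1).

Published percent-change magnitudes exist only as figure graphics, so the
tests assert the reported sign and ordering properties: increasing the renal
or non-renal clearance parameters lowers AUC with little effect on Cmax,
removing the blood-mass distribution narrows the band at the concentration
peak, and doubling versus halving the $V_{frac}$ CV widens versus narrows
the absorption-phase band.

## Problem sizes and reproducibility

Every stochastic entry point takes a mandatory seed and is bitwise
reproducible from it. The test suite runs its population checks at n = 1000
(the qualification size), Monte-Carlo distribution checks at n = 10^4 draws
per compartment, sensitivity ordering checks at 50–150 individuals per
scenario, and the recovery check at five replicate 20-subject trials — sizes
chosen so the whole suite completes on a single CPU in a few minutes while
keeping Monte-Carlo error well inside the asserted tolerances. The
acceptance script reruns the flow-identity, renal-fraction and recovery
computations from scratch at the same sizes.

## Known limitations

* Adult Caucasian males only; no correlation between organ masses beyond the
  shared height/weight/BSA drivers.
* Linear PK only: no target-mediated disposition, FcRn recycling or
  saturable clearance; single abdominal SC dose.
* The LDC volume depends only on injection volume, not on formulation
  viscosity or compound size.
* The between-subject CV from the two-stage fit conflates true variability
  with per-subject estimation noise; with rich sampling this inflation is
  modest but it is not corrected.
* Reference inputs that the source table does not print (flow fractions,
  vascular/interstitial volume fractions, reflection-coefficient bases,
  cardiac output, primate non-renal clearance, height distribution) are
  editable configuration with documented, literature-typical defaults;
  conclusions that hinge on their exact values should treat them as
  assumptions.
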