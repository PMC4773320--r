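population:
  reference_weight: 71.0
  reference_height: 172.0
  reference_bmi: 24.0
  allometric_exponent: 0.75
  bsa_a: 0.0235
  bsa_b: 0.515
  bsa_c: 0.422
  height_mean: 178.0
  height_cv: 0.04
  hematocrit_mean: 0.42
  hematocrit_cv: 0.02
  hematocrit_dist: lognormal
  ff_mean: 0.2
  ff_cv: 0.0294
  ff_dist: lognormal
  cardiac_output: 336000.0
  weight_filter:
  - 60.0
  - 80.0
  gfr_filter:
  - 90.0
  - 150.0
  acceptance_floor: 0.0001
  compartments:
  - name: adipose
    fraction_bw: 18.539999999999999
    cv: 0.43
    dist: lognormal
    scaling: height
  - name: brain
    fraction_bw: 1.968
    cv: 0.1
    dist: normal
    scaling: height
  - name: blood
    fraction_bw: 8.005000000000001
    cv: 0.22
    dist: lognormal
    scaling: weight
  - name: bone
    fraction_bw: 13.952
    cv: 0.14
    dist: normal
    scaling: height
  - name: heart
    fraction_bw: 0.448
    cv: 0.19
    dist: normal
    scaling: height
  - name: kidney
    fraction_bw: 0.421
    cv: 0.25
    dist: normal
    scaling: height
  - name: large_intestine
    fraction_bw: 1.52
    cv: 0.2
    dist: normal
    scaling: height
  - name: liver
    fraction_bw: 2.707
    cv: 0.23
    dist: normal
    scaling: height
  - name: lung
    fraction_bw: 1.569
    cv: 0.36
    dist: lognormal
    scaling: height
  - name: lymph
    fraction_bw: 0.359
    cv: 0.22
    dist: lognormal
    scaling: weight
  - name: muscle
    fraction_bw: 40.701999999999998
    cv: 0.16
    dist: lognormal
    scaling: height
  - name: other
    fraction_bw: 3.876000000000005
    cv: 0.2
    dist: normal
    scaling: height
  - name: pancreas
    fraction_bw: 0.136
    cv: 0.27
    dist: normal
    scaling: height
  - name: skin
    fraction_bw: 4.477
    cv: 0.1
    dist: lognormal
    scaling: bsa
  - name: small_intestine
    fraction_bw: 1.068
    cv: 0.12
    dist: normal
    scaling: height
  - name: spleen
    fraction_bw: 0.244
    cv: 0.56
    dist: lognormal
    scaling: height
  - name: thymus
    fraction_bw: 0.008
    cv: 0.05
    dist: lognormal
    scaling: height
  flow_fractions:
  - organ: adipose
    flow_fraction: 0.05
  - organ: brain
    flow_fraction: 0.12
  - organ: bone
    flow_fraction: 0.05
  - organ: heart
    flow_fraction: 0.04
  - organ: kidney
    flow_fraction: 0.19
  - organ: large_intestine
    flow_fraction: 0.04
  - organ: liver
    flow_fraction: 0.065
  - organ: lung
    flow_fraction: 0.025
  - organ: muscle
    flow_fraction: 0.17
  - organ: other
    flow_fraction: 0.0585
  - organ: pancreas
    flow_fraction: 0.01
  - organ: skin
    flow_fraction: 0.05
  - organ: small_intestine
    flow_fraction: 0.1
  - organ: spleen
    flow_fraction: 0.03
  - organ: thymus
    flow_fraction: 0.0015
drug:
  sigma_sf: 0.95
  sigma_i: 0.2
  lo: 0.002
  ls: 0.001
  fgfr: 0.001
  nrcl_primate: 1.9
  nrcl_ref_weight: 3.4
  nrcl_scaling_exponent: 1.0
  vfrac_mean: 0.25
  vfrac_cv: 0.68
  vfrac_dist: normal
  depot_drainage_mode: proportional
  organ_params:
  - organ: adipose
    sigma_v: 0.95
    fvv: 0.01
    fvic: 0.135
  - organ: brain
    sigma_v: 0.99
    fvv: 0.03
    fvic: 0.18
  - organ: bone
    sigma_v: 0.85
    fvv: 0.04
    fvic: 0.1
  - organ: heart
    sigma_v: 0.95
    fvv: 0.055
    fvic: 0.16
  - organ: kidney
    sigma_v: 0.9
    fvv: 0.105
    fvic: 0.2
  - organ: large_intestine
    sigma_v: 0.9
    fvv: 0.02
    fvic: 0.09
  - organ: liver
    sigma_v: 0.85
    fvv: 0.085
    fvic: 0.2
  - organ: lung
    sigma_v: 0.95
    fvv: 0.26
    fvic: 0.19
  - organ: muscle
    sigma_v: 0.95
    fvv: 0.026
    fvic: 0.12
  - organ: other
    sigma_v: 0.95
    fvv: 0.04
    fvic: 0.15
  - organ: pancreas
    sigma_v: 0.9
    fvv: 0.055
    fvic: 0.12
  - organ: skin
    sigma_v: 0.95
    fvv: 0.02
    fvic: 0.3
  - organ: small_intestine
    sigma_v: 0.9
    fvv: 0.02
    fvic: 0.094
  - organ: spleen
    sigma_v: 0.85
    fvv: 0.22
    fvic: 0.15
  - organ: thymus
    sigma_v: 0.9
    fvv: 0.055
    fvic: 0.15
trial:
  cohorts:
  - dose_mg: 45.0
    conc_mg_ml: 100.0
    n_subjects: 4
  - dose_mg: 90.0
    conc_mg_ml: 100.0
    n_subjects: 4
  - dose_mg: 180.0
    conc_mg_ml: 150.0
    n_subjects: 4
  - dose_mg: 360.0
    conc_mg_ml: 150.0
    n_subjects: 4
  - dose_mg: 720.0
    conc_mg_ml: 150.0
    n_subjects: 4
  sampling_times:
  - 0.5
  - 1.0
  - 2.0
  - 4.0
  - 8.0
  - 12.0
  - 24.0
  - 48.0
  - 72.0
  - 120.0
  - 168.0
  - 240.0
  - 336.0
  - 504.0
  - 672.0
  - 840.0
  - 1050.0
  loq: 1.0
  error_prop_cv: 0.15
  error_add_sd: 0.5
solver:
  atol: 1.0e-10
  rtol: 1.0e-08
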