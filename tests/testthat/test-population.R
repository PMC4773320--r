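test_that("allometric re-centering matches direct evaluation and is monotone", {
  # identity when the individual equals the reference
  expect_equal(recenter_mass_height(1.922, 172, 172, 0.75), 1.922)
  expect_equal(recenter_mass_weight(5.684, 71, 71, 0.75), 5.684)

  # direct evaluation oracles (liver 2.707% x 71 kg, blood 8.005% x 71 kg,
  # lymph 0.359% x 71 kg)
  expect_equal(recenter_mass_height(1.922, 160, 172, 0.75),
               1.922 * (160 / 172)^0.75)
  expect_equal(round(recenter_mass_height(1.922, 160, 172, 0.75), 3), 1.821)
  expect_equal(round(recenter_mass_weight(5.684, 80, 71, 0.75), 3), 6.216)
  expect_equal(round(recenter_mass_weight(0.255, 60, 71, 0.75), 3), 0.225)

  # strictly increasing in the driver
  h <- seq(150, 200, by = 5)
  expect_true(all(diff(recenter_mass_height(1.922, h, 172)) > 0))
  expect_true(all(diff(recenter_mass_weight(5.684, seq(55, 95, 5), 71)) > 0))

  expect_error(recenter_mass_height(1.922, 0, 172), class = "lymphpbpk_domain_error")
  expect_error(recenter_mass_weight(-1, 70, 71), class = "lymphpbpk_domain_error")
})

test_that("body surface area follows the Gehan-George power law", {
  expect_equal(bsa(71, 172), 0.0235 * 71^0.515 * 172^0.422)
  expect_equal(round(bsa(71, 172), 2), 1.85)
  expect_gt(bsa(1e-4, 1e-4), 0)
  # power-law identity in weight
  expect_equal(bsa(4 * 71, 172), 4^0.515 * bsa(71, 172))
  expect_error(bsa(0, 172), class = "lymphpbpk_domain_error")
})

test_that("skin mass scales linearly with BSA", {
  b0 <- bsa(71, 172)
  expect_equal(recenter_mass_skin(3.179, b0, b0), 3.179)
  expect_equal(recenter_mass_skin(3.179, 2 * b0, b0), 6.358)
  expect_equal(recenter_mass_skin(3.179, bsa(80, 180), b0),
               3.179 * bsa(80, 180) / b0)
})

test_that("compartment sampling honors mean, CV, truncation and floor", {
  expect_identical(sample_compartment_mass(2.5, 0, "normal", n = 10),
                   rep(2.5, 10))

  set.seed(1)
  x <- sample_compartment_mass(1, 0.5, "normal", n = 1e5)
  expect_gte(min(x), 0.1)  # floored at mean/10

  # log-normal matched to arithmetic mean/CV (untruncated draws)
  set.seed(2)
  y <- sample_compartment_mass(1, 0.22, "lognormal", n = 1e5,
                               truncate = FALSE, floor = FALSE)
  expect_equal(mean(y), 1, tolerance = 0.01)
  expect_equal(sd(y) / mean(y), 0.22, tolerance = 0.02)

  # central-95% truncation shifts a skewed log-normal mean down only modestly
  set.seed(3)
  z <- sample_compartment_mass(1, 0.56, "lognormal", n = 1e5)
  expect_equal(mean(z), 1, tolerance = 0.05)
  expect_lt(mean(z), 1)

  expect_error(sample_compartment_mass(1, 0.2, "uniform"),
               class = "lymphpbpk_config_error")
})

test_that("flow derivation reproduces the reference perfusion identities", {
  spec <- test_spec()
  drug <- test_drug()
  ref <- test_ref()

  # reference masses -> reference organ blood flows (fraction of CO)
  ff <- spec$flow_fractions
  for (org in c("skin", "liver", "kidney", "brain")) {
    expect_equal(ref[[paste0("qb_", org)]],
                 spec$cardiac_output * ff$flow_fraction[ff$organ == org])
  }
  # lymph-flow fractions of blood flow: 0.1% skin, 0.2% elsewhere
  expect_equal(ref$lymph_flow_skin / ref$qb_skin, 0.001)
  expect_equal(ref$lymph_flow_liver / ref$qb_liver, 0.002)
  expect_equal(ref$lymph_flow_muscle / ref$qb_muscle, 0.002)

  # hct = 0 -> plasma flow equals blood flow
  ind0 <- ref
  ind0$hematocrit <- 0
  ind0 <- derive_flows(ind0, spec, drug)
  expect_equal(ind0$qp_liver, ind0$qb_liver)

  expect_error(derive_flows(ref[, setdiff(names(ref), "mass_liver")],
                            spec, drug),
               class = "lymphpbpk_config_error")
})

test_that("GFR is renal plasma flow times filtration fraction", {
  ind <- test_ref()
  ind$filtration_fraction <- 0
  expect_equal(derive_gfr(ind)$gfr_ml_min, 0)

  ind$qp_kidney <- 600 * 60  # 600 mL/min as mL/h
  ind$filtration_fraction <- 0.20
  expect_equal(derive_gfr(ind)$gfr_ml_min, 120)

  # doubling kidney mass at fixed perfusion doubles GFR
  spec <- test_spec(); drug <- test_drug()
  ind2 <- test_ref()
  ind2$mass_kidney <- 2 * ind2$mass_kidney
  ind2 <- derive_gfr(derive_flows(ind2, spec, drug))
  expect_equal(ind2$gfr_ml_min, 2 * test_ref()$gfr_ml_min)
})

test_that("generated populations close mass balance and obey the filters", {
  pop <- test_pop()
  spec <- test_spec()

  expect_equal(pop$weight_kg,
               rowSums(as.data.frame(pop)[, mass_columns()]),
               tolerance = 1e-12)
  # blood partition: venous + arterial = blood, ratio exactly 2:1
  expect_equal(pop$venous_kg + pop$arterial_kg, pop$blood_kg,
               tolerance = 1e-14)
  expect_equal(pop$venous_kg / pop$arterial_kg, rep(2, nrow(pop)))

  expect_true(all(pop$weight_kg >= spec$weight_filter[1] &
                    pop$weight_kg <= spec$weight_filter[2]))
  expect_true(all(pop$gfr_ml_min >= spec$gfr_filter[1] &
                    pop$gfr_ml_min <= spec$gfr_filter[2]))

  # normal-sampled organ masses respect the mean/10 floor relative to their
  # re-centered means (floor applied during sampling; spot-check kidney)
  expect_true(all(pop$mass_kidney > 0))

  # filter idempotence: re-applying the filters removes no one
  keep <- pop$weight_kg >= spec$weight_filter[1] &
    pop$weight_kg <= spec$weight_filter[2] &
    pop$gfr_ml_min >= spec$gfr_filter[1] &
    pop$gfr_ml_min <= spec$gfr_filter[2]
  expect_true(all(keep))
})

test_that("population generation is bitwise reproducible by seed", {
  p1 <- generate_population(20, test_spec(), test_drug(), seed = 99)
  p2 <- generate_population(20, test_spec(), test_drug(), seed = 99)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- generate_population(20, test_spec(), test_drug(), seed = 100)
  expect_false(identical(p1$height_cm, p3$height_cm))
})

test_that("an impossible filter fails fast naming the filter", {
  spec <- population_spec(weight_filter = c(200, 201))
  expect_error(generate_population(5, spec, test_drug(), seed = 1),
               "weight_filter", class = "lymphpbpk_acceptance_error")
})

test_that("the reference individual reproduces the reference anthropometry", {
  ref <- test_ref()
  spec <- test_spec()
  expect_equal(ref$weight_kg, 71)
  expect_equal(ref$height_cm, 172, tolerance = 1e-4)  # from weight and BMI
  expect_equal(ref$bmi_kg_m2, 24, tolerance = 1e-4)
  expect_equal(sum(spec$compartments$fraction_bw), 100, tolerance = 1e-12)
})
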