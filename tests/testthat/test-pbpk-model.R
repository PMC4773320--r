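test_that("dose events book injection and LDC volumes correctly", {
  d1 <- dose_event(720, 150, vfrac = 0.25)
  expect_equal(d1$injection_volume_ml, 4.8)
  expect_equal(d1$ldc_volume_ml, 1.2)
  expect_equal(d1$n_injections, 3)  # 4.8 mL split at <= 2 mL per injection

  d2 <- dose_event(45, 100, vfrac = 0.25)
  expect_equal(d2$injection_volume_ml, 0.45)
  expect_equal(d2$n_injections, 1)

  expect_warning(dose_event(10, 100), "outside")
})

test_that("model build enforces reflection-coefficient and volume invariants", {
  drug <- test_drug()
  ref <- test_ref()
  dose <- dose_event(45, 100)

  bad <- drug
  bad$sigma_sf <- 1.2  # brain sigma_v 0.99 -> effective 1.188
  expect_error(build_pbpk_model(ref, bad, dose), "brain",
               class = "lymphpbpk_config_error")

  expect_error(drug_params(sigma_sf = 1.2), "brain",
               class = "lymphpbpk_config_error")

  # an injection larger than the skin interstitial space cannot be built
  huge <- suppressWarnings(dose_event(2e5, 100))
  expect_error(build_pbpk_model(ref, drug, huge),
               class = "lymphpbpk_config_error")
})

test_that("depot drainage flow follows the volume-proportional rule", {
  drug <- test_drug()
  ref <- test_ref()
  dose <- dose_event(45, 100)
  m <- build_pbpk_model(ref, drug, dose)

  v_int_skin <- drug$organ_params$fvic[drug$organ_params$organ == "skin"] *
    ref$mass_skin * 1000
  l_skin <- drug$ls * ref$qb_skin
  expect_equal(m$q_dep_ml_h, l_skin * 0.45 / v_int_skin)

  # full-drainage mode: depot drains at the entire skin lymph flow
  drug_full <- drug_params(depot_drainage_mode = "full")
  m2 <- build_pbpk_model(reference_individual(test_spec(), drug_full),
                         drug_full, dose)
  expect_equal(m2$q_dep_ml_h, l_skin)
})

test_that("a fully reflecting lymphatic wall freezes the depot", {
  drug <- test_drug()
  drug$sigma_i <- 1
  m <- build_pbpk_model(test_ref(), drug, dose_event(45, 100))
  sim <- simulate_pbpk(m, c(1, 10, 100, 1000))
  expect_equal(unname(sim$amounts[, "skin_depot"]), rep(45000, 4),
               tolerance = 1e-9)
})

test_that("mass is conserved with and without clearance", {
  drug <- test_drug()
  drug$nrcl_primate <- 0
  m <- build_pbpk_model(test_ref(), drug, dose_event(45, 100),
                        overrides = list(fgfr = 0))
  sim <- simulate_pbpk(m, trial_times())
  # no clearance: everything stays in the body
  expect_equal(unname(rowSums(sim$amounts)), rep(45000, length(sim$times)),
               tolerance = 1e-9)
  expect_equal(unname(sim$amounts[, "cleared_renal"]),
               rep(0, length(sim$times)))

  # with clearance: body + cumulative cleared accounts for the dose
  sim2 <- simulate_pbpk(build_pbpk_model(test_ref(), test_drug(),
                                         dose_event(45, 100)),
                        trial_times())
  expect_lte(max(abs(sim2$mass_balance_residual)), 1e-6)
  expect_gt(sim2$amounts[length(sim2$times), "cleared_renal"], 0)
})

test_that("the system is linear in dose", {
  tt <- trial_times()
  s1 <- simulate_pbpk(build_pbpk_model(test_ref(), test_drug(),
                                       suppressWarnings(dose_event(45, 100))),
                      tt)
  s2 <- simulate_pbpk(build_pbpk_model(test_ref(), test_drug(),
                                       suppressWarnings(dose_event(90, 200))),
                      tt)  # same injection volume, double dose
  expect_equal(s2$amounts, 2 * s1$amounts, tolerance = 1e-7)
  expect_equal(s2$profile$conc, 2 * s1$profile$conc, tolerance = 1e-7)
})

test_that("the integrator matches a hand-derived closed-form transit chain", {
  # depot -> plasma -> eliminated, first-order: Bateman solution
  k1 <- 0.05
  k2 <- 0.01
  states <- c("skin_depot", "venous", "cleared_renal")
  M <- matrix(0, 3, 3, dimnames = list(states, states))
  M["skin_depot", "skin_depot"] <- -k1
  M["venous", "skin_depot"] <- k1
  M["venous", "venous"] <- -k2
  M["cleared_renal", "venous"] <- k2
  fake <- structure(
    list(M = M, volumes = c(skin_depot = 1, venous = 3000, cleared_renal = 1),
         states = states, dose = dose_event(45, 100), include_ldc = FALSE),
    class = "pbpk_model"
  )
  tt <- c(1, 5, 10, 50, 100, 500)
  sim <- simulate_pbpk(fake, tt)
  D <- 45000
  depot <- D * exp(-k1 * tt)
  venous <- D * k1 / (k2 - k1) * (exp(-k1 * tt) - exp(-k2 * tt))
  expect_equal(unname(sim$amounts[, "skin_depot"]), depot, tolerance = 1e-6)
  expect_equal(unname(sim$amounts[, "venous"]), venous, tolerance = 1e-6)
})

test_that("the integrator matches a matrix-exponential solution of the full system", {
  skip_if_not_installed("Matrix")
  m <- build_pbpk_model(test_ref(), test_drug(), dose_event(45, 100))
  y0 <- stats::setNames(numeric(length(m$states)), m$states)
  y0["skin_depot"] <- 45000
  tt <- c(2, 24, 168, 1050)
  sim <- simulate_pbpk(m, tt)
  for (i in seq_along(tt)) {
    ex <- as.numeric(Matrix::expm(m$M * tt[i]) %*% y0)
    expect_equal(unname(sim$amounts[i, ]), ex, tolerance = 1e-6)
  }
})

test_that("solutions are converged with respect to solver tolerances", {
  m <- build_pbpk_model(test_ref(), test_drug(), dose_event(45, 100))
  tt <- trial_times()
  loose <- simulate_pbpk(m, tt)
  tight <- simulate_pbpk(m, tt, atol = 1e-11, rtol = 1e-9)
  expect_equal(loose$profile$conc, tight$profile$conc, tolerance = 1e-3)
})

test_that("omitting the LDC uniformly raises early plasma concentrations", {
  tt <- c(0.5, 1, 2, 4, 6, 8, 10)
  with_ldc <- simulate_pbpk(
    build_pbpk_model(test_ref(), test_drug(), dose_event(45, 100)), tt
  )$profile$conc
  without <- simulate_pbpk(
    build_pbpk_model(test_ref(), test_drug(), dose_event(45, 100),
                     include_ldc = FALSE), tt
  )$profile$conc
  expect_true(all(without >= with_ldc))
  expect_gt(max(without - with_ldc), 0)
})

test_that("plasma declines monotonically after Tmax", {
  tt <- c(seq(0.5, 48, by = 0.5), seq(50, 1050, by = 5))
  sim <- simulate_pbpk(build_pbpk_model(test_ref(), test_drug(),
                                        dose_event(45, 100)), tt)
  conc <- sim$profile$conc
  i_max <- which.max(conc)
  expect_true(all(diff(conc[i_max:length(conc)]) < 0))
})

test_that("plasma_profile censors at the limit of quantitation", {
  sim <- simulate_pbpk(build_pbpk_model(test_ref(), test_drug(),
                                        dose_event(45, 100)), trial_times())
  pr <- plasma_profile(sim, loq = 1)
  expect_identical(pr$blq, pr$conc < 1)
  expect_true(any(pr$blq) && any(!pr$blq))
})
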