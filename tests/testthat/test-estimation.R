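make_medians <- function(cohort, time, conc) {
  tibble::tibble(cohort = cohort, time = time, conc = conc)
}

test_that("the median-deviation objective averages absolute deviations", {
  obs <- make_medians(rep(1:2, each = 2), rep(c(12, 24), 2), c(4, 6, 8, 10))
  expect_equal(objective_median_deviation(obs, obs), 0)

  pred <- obs
  pred$conc <- obs$conc + 0.7  # constant offset
  expect_equal(objective_median_deviation(pred, obs), 0.7)

  # two cohorts with deviations {1, 3} and {2, 2}: mean over 4 points is 2
  pred2 <- obs
  pred2$conc <- obs$conc + c(1, 3, 2, 2)
  expect_equal(objective_median_deviation(pred2, obs), 2)

  # invariant to row ordering
  expect_equal(objective_median_deviation(pred2[c(3, 1, 4, 2), ], obs), 2)

  # mismatched grids are refused rather than interpolated
  expect_error(
    objective_median_deviation(pred2[-1, ], obs),
    class = "lymphpbpk_alignment_error"
  )
  bad <- obs
  bad$time[1] <- 13
  expect_error(objective_median_deviation(bad, obs),
               class = "lymphpbpk_alignment_error")
})

noise_free_obs <- function(vfrac_true = 0.25,
                           cohorts = data.frame(dose_mg = c(45, 720),
                                                conc_mg_ml = c(100, 150))) {
  ref <- test_ref()
  drug <- test_drug()
  tt <- trial_times()
  out <- lapply(seq_len(nrow(cohorts)), function(k) {
    d <- dose_event(cohorts$dose_mg[k], cohorts$conc_mg_ml[k], vfrac_true)
    sim <- simulate_pbpk(build_pbpk_model(ref, drug, d), tt)
    tibble::tibble(subject_id = k, dose_mg = cohorts$dose_mg[k],
                   conc_mg_ml = cohorts$conc_mg_ml[k], time = tt,
                   conc = sim$profile$conc, blq = FALSE)
  })
  dplyr::bind_rows(out)
}

test_that("noise-free data return the generating Vfrac in both weightings", {
  obs <- noise_free_obs(0.25)
  f_log <- fit_vfrac(obs, test_spec(), test_drug())
  expect_equal(f_log$vfrac, 0.25, tolerance = 0.01)
  f_wls <- fit_vfrac(obs, test_spec(), test_drug(), weighting = "combined")
  expect_equal(f_wls$vfrac, 0.25, tolerance = 0.01)
  expect_s3_class(tidy(f_log), "tbl_df")
  expect_equal(tidy(f_log)$estimate[1], f_log$vfrac)
  expect_equal(glance(f_log)$mode, "pooled")
})

test_that("the fit is invariant to subject order and joint dose scaling", {
  obs <- noise_free_obs(0.3)
  base <- fit_vfrac(obs, test_spec(), test_drug())$vfrac

  shuffled <- obs[rev(seq_len(nrow(obs))), ]
  expect_equal(fit_vfrac(shuffled, test_spec(), test_drug())$vfrac, base,
               tolerance = 1e-6)

  # scaling dose, injected concentration and measured concentrations jointly
  # leaves the dose-normalized problem unchanged
  scaled <- obs
  scaled$dose_mg <- obs$dose_mg * 2
  scaled$conc_mg_ml <- obs$conc_mg_ml * 2
  scaled$conc <- obs$conc * 2
  expect_equal(fit_vfrac(scaled, test_spec(), test_drug())$vfrac, base,
               tolerance = 1e-6)
})

test_that("two-stage mode reports per-subject estimates and their spread", {
  obs <- dplyr::bind_rows(
    dplyr::mutate(noise_free_obs(0.2,
                                 data.frame(dose_mg = 45, conc_mg_ml = 100)),
                  subject_id = 1),
    dplyr::mutate(noise_free_obs(0.4,
                                 data.frame(dose_mg = 45, conc_mg_ml = 100)),
                  subject_id = 2)
  )
  f <- fit_vfrac(obs, test_spec(), test_drug(), mode = "two_stage")
  expect_equal(sort(f$per_subject$vfrac), c(0.2, 0.4), tolerance = 0.01)
  expect_equal(f$vfrac, 0.3, tolerance = 0.01)
  expect_equal(f$vfrac_cv, sd(c(0.2, 0.4)) / 0.3, tolerance = 0.05)
})

test_that("subjects without enough quantifiable points are excluded loudly", {
  obs <- noise_free_obs(0.25)
  blq_subject <- dplyr::mutate(
    noise_free_obs(0.25, data.frame(dose_mg = 45, conc_mg_ml = 100)),
    subject_id = 99, blq = TRUE
  )
  expect_warning(
    f <- fit_vfrac(dplyr::bind_rows(obs, blq_subject),
                   test_spec(), test_drug()),
    "99"
  )
  expect_equal(f$n_subjects, 2)
})

test_that("including the LDC reduces the median-deviation objective", {
  # small noise-free synthetic study: observations generated with the LDC
  design <- trial_design(
    cohorts = tibble::tibble(dose_mg = c(45, 720), conc_mg_ml = c(100, 150),
                             n_subjects = c(3L, 3L)),
    error_prop_cv = 0, error_add_sd = 0, loq = 0
  )
  tr <- generate_trial(design, test_spec(), test_drug(), seed = 77)
  obs_med <- cohort_medians(tr)

  # model-predicted cohort medians from a small paired population
  pop <- generate_population(30, test_spec(), test_drug(), seed = 78)
  tt <- design$sampling_times
  pred_med <- function(include_ldc) {
    dplyr::bind_rows(lapply(seq_len(nrow(design$cohorts)), function(k) {
      co <- design$cohorts[k, ]
      conc <- population_profiles(pop, test_drug(), co$dose_mg, co$conc_mg_ml,
                                  tt, include_ldc = include_ldc)
      tibble::tibble(cohort = k, time = tt,
                     conc = apply(conc, 1, median))
    }))
  }
  with_ldc <- objective_median_deviation(pred_med(TRUE), obs_med)
  without <- objective_median_deviation(pred_med(FALSE), obs_med)
  expect_lt(with_ldc, without)
})
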