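test_that("noiseless series reproduce the model profile exactly", {
  p <- id71_params()
  times <- clinical_sampling_times(6)
  s <- generate_patient_series(p, 0.4, times = times, noise_sd = 0, seed = 1)
  tr <- simulate_resection(p, 0.4, horizon = max(times), times = c(0, times))
  expect_equal(s$volume_fraction, tr$N[-1])
  expect_equal(attr(s, "resection_fraction"), 0.4)
  expect_identical(as.numeric(attr(s, "truth")), as.numeric(p))
})

test_that("series are seed-determined with multiplicative lognormal noise", {
  p <- id71_params()
  a <- generate_patient_series(p, 0.5, noise_sd = 0.05, seed = 7)
  b <- generate_patient_series(p, 0.5, noise_sd = 0.05, seed = 7)
  d <- generate_patient_series(p, 0.5, noise_sd = 0.05, seed = 8)
  expect_identical(a, b)
  expect_false(any(a$volume_fraction == d$volume_fraction))
  # pooled log-residual spread matches the requested noise level
  times <- clinical_sampling_times(6)
  tr <- simulate_resection(p, 0.5, horizon = max(times), times = c(0, times))
  resid <- unlist(lapply(1:300, function(i) {
    s <- generate_patient_series(p, 0.5, times = times, noise_sd = 0.05,
                                 seed = 1000 + i)
    log(s$volume_fraction / tr$N[-1])
  }))
  expect_equal(sd(resid), 0.05, tolerance = 0.05)
  expect_lt(abs(mean(resid)), 0.005)
})

test_that("cohorts obey their generating spec", {
  spec <- synthetic_cohort_spec(n_patients = 27)
  cohort <- generate_cohort(spec, seed = 21)
  expect_length(cohort, 27)
  for (s in cohort) {
    rf <- attr(s, "resection_fraction")
    expect_true(rf >= 0.30 && rf <= 0.70)
    expect_true(nrow(s) >= 4 && nrow(s) <= 8)
    # first observation consistent with the remnant fraction
    expect_lt(abs(s$volume_fraction[1] - (1 - rf)), 0.2)
    cov <- attr(s, "covariates")
    expect_gte(cov$bmi, 15)
    expect_true(cov$sex %in% c("M", "F"))
    expect_equal(cov$height_m, if (cov$sex == "M") 1.72 else 1.58)
    tr <- attr(s, "truth")
    # only the jittered parameters move, within their fold range
    expect_true(abs(log(tr[["M"]] / 5.8206)) <= log(sqrt(2)) + 1e-9)
    expect_identical(tr[["k_IL6"]], 1.4528)
  }
  # seed isolation
  again <- generate_cohort(spec, seed = 21)
  other <- generate_cohort(spec, seed = 22)
  expect_identical(lapply(cohort, c), lapply(again, c))
  expect_false(any(cohort[[1]]$volume_fraction %in%
                   other[[1]]$volume_fraction))
  # degenerate jitter collapses all truths onto the reference
  flat <- generate_cohort(synthetic_cohort_spec(n_patients = 3,
                                                jitter_folds = c(M = 1)),
                          seed = 4)
  expect_identical(as.numeric(attr(flat[[1]], "truth")),
                   as.numeric(attr(flat[[3]], "truth")))
})

test_that("full-recovery predicate supports both clinical windows", {
  s <- fake_series <- structure(
    data.frame(time_days = c(100, 900), volume_fraction = c(0.6, 0.95)),
    class = c("hep_series", "data.frame"), resection_fraction = 0.4)
  expect_true(recovered_fully(s))
  expect_true(recovered_fully(s, window = c(0.9, 1.0)))
  s$volume_fraction[2] <- 1.05
  expect_true(recovered_fully(s))
  expect_false(recovered_fully(s, window = c(0.9, 1.0)))
  s$volume_fraction[2] <- 0.7
  expect_false(recovered_fully(s))
})

test_that("patient-series CSV dialect round-trips", {
  cohort <- generate_cohort(synthetic_cohort_spec(n_patients = 3), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_patient_series(cohort, f)
  back <- read_patient_series(f)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$volume_fraction, cohort[[i]]$volume_fraction)
    expect_equal(attr(back[[i]], "resection_fraction"),
                 attr(cohort[[i]], "resection_fraction"))
  }
  unlink(f)
})

test_that("noiseless round trip recovers the identifiable parameters", {
  p <- id71_params()
  truth <- set_params(p, M = 5.0, k_G = 9e-4, beta_ap = 0.005)
  s <- generate_patient_series(truth, 0.55,
                               times = clinical_sampling_times(6),
                               noise_sd = 0, seed = 1)
  init <- set_params(p, M = metabolic_load_cook(65000),
                     k_G = k_G_cook_human())
  f <- fit_parameters(s, init, free = c("M", "k_G", "beta_ap"),
                      lambda = 1e-4, n_starts = 6, maxit = 300)
  expect_lt(abs(f$params[["M"]] - truth[["M"]]) / truth[["M"]], 0.1)
  expect_lt(abs(f$params[["k_G"]] - truth[["k_G"]]) / truth[["k_G"]], 0.1)
})
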