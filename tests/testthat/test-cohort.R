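test_that("cohort designs vary only the requested parameters", {
  ref <- id71_params()
  co <- sobol_cohort(c("M", "beta_ap"), n = 16, reference = ref)
  expect_length(co, 16)
  d <- attr(co, "design")
  expect_identical(colnames(d), c("M", "beta_ap"))
  b <- default_cohort_bounds()
  expect_true(all(d[, "M"] >= b$M[1] & d[, "M"] <= b$M[2]))
  expect_true(all(d[, "beta_ap"] >= b$beta_ap[1] & d[, "beta_ap"] <= b$beta_ap[2]))
  fixed <- setdiff(hep_param_names, c("M", "beta_ap"))
  for (i in c(1, 8, 16))
    expect_identical(as.numeric(co[[i]][fixed]), as.numeric(ref[fixed]))
  # bit-identical reruns
  expect_identical(attr(sobol_cohort("M", n = 10), "design"),
                   attr(sobol_cohort("M", n = 10), "design"))
  expect_error(sobol_cohort("not_a_param", n = 5), "unknown")
  expect_error(sobol_cohort("M", bounds = list(M = c(2, 2)), n = 5),
               "invalid bounds")
})

test_that("mode sweeps classify every virtual patient", {
  co <- sobol_cohort(c("M", "beta_ap"), n = 12)
  mm <- sweep_modes(co, 2 / 3)
  expect_equal(nrow(mm), 12)
  expect_true(all(c("patient", "M", "beta_ap", "mode", "N_730", "N_912.5")
                  %in% names(mm)))
  expect_true(all(mm$mode %in% c("normal", "suppressed", "failure",
                                 "unresponsive", "error")))
  expect_false(any(mm$mode == "error"))
})

test_that("single-parameter influence classes match the one-at-a-time analysis", {
  expect_influence <- function(name, outcome, sens) {
    ic <- classify_parameter_influence(name)
    expect_identical(ic$outcome_class, outcome)
    expect_identical(ic$sensitivity, sens)
  }
  expect_influence("k_GF", "recovery-only", "sensitive-improves")
  expect_influence("kappa_JAK", "recovery-only", "sensitive-decelerates")
  expect_influence("kappa_ST3", "recovery-only", "insensitive")
  expect_influence("M", "recovery-and-failure", "sensitive")
  expect_error(classify_parameter_influence("M", n_levels = 3), "5")
})

test_that("polynomial SVM separates the mode regions", {
  set.seed(5)
  blob <- rbind(cbind(rnorm(40, 2, 0.3), rnorm(40, 0.02, 0.003)),
                cbind(rnorm(40, 8, 0.3), rnorm(40, 0.08, 0.003)))
  labels <- rep(c("normal", "failure"), each = 40)
  db <- decision_boundary(blob, labels)
  expect_equal(db$training_accuracy, 1)
  # decision sign separates the two blobs
  expect_true(all(db$decision(blob[1:40, ]) > 0))
  expect_true(all(db$decision(blob[41:80, ]) < 0))
  # permuted labels carry no signal beyond the class prior
  perm <- sample(labels)
  dbp <- decision_boundary(blob, perm)
  expect_lt(dbp$training_accuracy, 0.85)
  expect_error(decision_boundary(blob, rep("normal", 80)), "both")
})

test_that("recovery-region extent is a Monte-Carlo area fraction", {
  mm <- data.frame(mode = c(rep("normal", 6), rep("failure", 2),
                            rep("suppressed", 2)))
  expect_equal(recovery_region_extent(mm), 0.6)
  expect_equal(recovery_region_extent(data.frame(mode = rep("normal", 5))), 1)
  expect_error(recovery_region_extent(data.frame(mode = character(0))),
               "empty")
})

test_that("threshold map partitions into bistable and none-safe zones", {
  tm <- threshold_map(M_bounds = c(1, 12), beta_bounds = c(0.005, 0.08),
                      n_per_axis = 4)
  expect_equal(dim(tm$threshold), c(4, 4))
  expect_true(all(tm$status %in% c("threshold", "none-safe", "none-found")))
  expect_true(any(tm$status == "none-safe"))
  expect_true(any(tm$status == "threshold"))
  finite_thr <- tm$threshold[tm$status == "threshold"]
  expect_true(all(finite_thr >= 5 & finite_thr <= 90))
  # monotone: threshold non-increasing in M (rows) and beta_ap (cols),
  # counting none-safe as below and none-found as above the scan range
  num <- ifelse(tm$status == "none-safe", 4,
                ifelse(tm$status == "none-found", 95, tm$threshold))
  expect_true(all(apply(num, 2, function(col) all(diff(col) <= 0))))
  expect_true(all(apply(num, 1, function(row) all(diff(row) <= 0))))
  df <- as.data.frame(tm)
  expect_equal(nrow(df), 16)
  expect_true(all(c("M", "beta_ap", "threshold_pct", "status") %in% names(df)))
})
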