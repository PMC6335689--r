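test_that("mode rules are applied in their stated order", {
  tms <- c(0, 100, 365, 730, 912.5)
  # failure: below 0.1 at two years, whatever happens later
  tr <- fake_trajectory(tms, c(0.3, 0.2, 0.12, 0.05, 0.04), 0.7)
  expect_identical(classify_response(tr)$label, "failure")
  # normal: inside [0.9, 1.1] at 2.5 years
  tr <- fake_trajectory(tms, c(0.33, 0.5, 0.7, 0.85, 0.95), 2 / 3)
  expect_identical(classify_response(tr)$label, "normal")
  # suppressed: recovered but short of the normal window
  tr <- fake_trajectory(tms, c(0.33, 0.5, 0.6, 0.7, 0.75), 2 / 3)
  expect_identical(classify_response(tr)$label, "suppressed")
  # unresponsive: flat at the remnant level
  tr <- fake_trajectory(tms, rep(0.65, 5), 0.35)
  expect_identical(classify_response(tr)$label, "unresponsive")
  # the flat tolerance is configurable
  tr <- fake_trajectory(tms, c(0.65, 0.652, 0.654, 0.655, 0.655), 0.35)
  expect_identical(classify_response(tr)$label, "unresponsive")
  expect_identical(classify_response(tr, delta_flat = 1e-4)$label,
                   "suppressed")
  # short trajectories cannot be classified
  tr <- fake_trajectory(c(0, 365, 730), c(0.3, 0.5, 0.6), 0.7)
  expect_error(classify_response(tr), "912.5")
})

test_that("threshold scan reports the lowest failing level", {
  p <- id71_params()
  t12 <- threshold_of_failure(set_params(p, M = 12))
  expect_identical(t12$status, "threshold")
  expect_equal(t12$threshold_pct, 57)
  # refining the grid moves the threshold by at most one original step
  t12f <- threshold_of_failure(set_params(p, M = 12),
                               grid = seq(0.05, 0.90, by = 0.005))
  expect_lte(abs(t12f$threshold_pct - t12$threshold_pct), 1)
  # no safe level when the smallest scanned level already fails
  t22 <- threshold_of_failure(set_params(p, M = 22))
  expect_identical(t22$status, "none-safe")
  # no failure anywhere on a truncated grid
  tlow <- threshold_of_failure(set_params(p, M = 4),
                               grid = seq(0.05, 0.50, by = 0.01))
  expect_identical(tlow$status, "none-found")
  expect_true(is.na(tlow$threshold_pct))
  expect_error(threshold_of_failure(p, grid = c(0.5, 0.3)), "sorted")
})

test_that("trajectories bracketing the threshold diverge to the two attractors", {
  p <- set_params(id71_params(), M = 12)
  lo <- simulate_resection(p, 0.56, horizon = attractor_horizon(),
                           times = c(0, 730, attractor_horizon()))
  hi <- simulate_resection(p, 0.57, horizon = attractor_horizon(),
                           times = c(0, 730, attractor_horizon()))
  expect_gt(lo$N[3] - hi$N[3], 0.5)
})

test_that("phase portraits resolve the two basins and the critical level", {
  p <- set_params(id71_params(), M = 4)
  pp <- phase_portrait(p, levels = c(0.30, 0.86, 0.87, 0.90),
                       horizon = 36500)
  expect_equal(pp$critical_resection, 0.87)
  expect_true(all(pp$curves$Q >= 0) && all(pp$curves$R >= 0))
  term <- function(lv) {
    cv <- pp$curves[pp$curves$resection == lv, ]
    cv[nrow(cv), ]
  }
  # recovery side: ends near the pre-resection attractor
  t30 <- term(0.30)
  expect_lt(t30$R, 0.01)
  expect_lt(abs(t30$N - 0.99), 0.05)
  # failure side: ends at the origin
  t90 <- term(0.90)
  expect_lt(t90$Q + t90$R, 0.01)
  expect_error(phase_portrait(p, levels = 0.5), "two")
})
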