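test_that("objective vanishes on self-generated noise-free data and orders parameters", {
  net0 <- ref_net()
  truth <- default_calibration()
  ds <- zero_noise_cohort(n = 4, seed = 7, truth = truth, network = net0)
  o_truth <- calibration_objective(truth$k_ref, truth$n_sub, ds, net0)
  expect_lt(o_truth, 1e-8)
  # any perturbation of either constant increases the objective
  expect_gt(calibration_objective(truth$k_ref * 1.6, truth$n_sub, ds, net0),
            o_truth + 0.1)
  expect_gt(calibration_objective(truth$k_ref / 1.6, truth$n_sub, ds, net0),
            o_truth + 0.1)
  expect_gt(calibration_objective(truth$k_ref, 8, ds, net0), o_truth + 0.5)
  # objective is invariant to patient ordering
  perm <- subset_cohort(ds, c(3, 1, 4, 2))
  expect_equal(calibration_objective(truth$k_ref, truth$n_sub, perm, net0),
               o_truth)
  expect_gte(o_truth, 0)
})

test_that("HU coefficient fit is exact for one patient and homogeneous", {
  net0 <- ref_net()
  truth <- default_calibration()
  ds <- zero_noise_cohort(n = 3, seed = 5, truth = truth, network = net0)
  timing <- list(k_ref = truth$k_ref, n_sub = truth$n_sub)
  kap <- fit_hu_coefficient(ds, timing, net0)
  expect_equal(as.numeric(kap), 25, tolerance = 1e-6)
  one <- subset_cohort(ds, 1)
  kap1 <- fit_hu_coefficient(one, timing, net0)
  # single patient, exact model: kappa is the measured/simulated peak ratio
  expect_equal(as.numeric(kap1), 25, tolerance = 1e-6)
  # doubling all measured PCTN doubles the fitted coefficient
  ds2 <- ds; ds2$metrics$pctn <- ds$metrics$pctn * 2
  expect_equal(as.numeric(fit_hu_coefficient(ds2, timing, net0)),
               2 * as.numeric(kap), tolerance = 1e-9)
  # L1 variant agrees on exact data
  expect_equal(as.numeric(fit_hu_coefficient(ds, timing, net0, norm = "l1")),
               25, tolerance = 1e-6)
})

test_that("timing fit recovers truth from noise-free data on a narrowed grid", {
  net0 <- ref_net()
  truth <- default_calibration()
  ds <- zero_noise_cohort(n = 4, seed = 7, truth = truth, network = net0)
  fit <- fit_timing(ds, n_sub_grid = c(10, 15, 20), k_bounds = c(0.2, 6),
                    network = net0)
  expect_equal(fit$n_sub, 15)
  expect_lt(abs(fit$k_ref / truth$k_ref - 1), 0.05)
  expect_false(fit$low_confidence)
})

test_that("degenerate datasets are flagged but still fitted", {
  net0 <- ref_net()
  ds <- zero_noise_cohort(n = 2, seed = 9, network = net0)
  one <- subset_cohort(ds, 1)
  expect_warning(
    fit <- fit_timing(one, n_sub_grid = 15, k_bounds = c(0.5, 3),
                      network = net0),
    "low-confidence")
  expect_true(fit$low_confidence)
  expect_true(is.finite(fit$k_ref) && fit$k_ref > 0)
  dup <- subset_cohort(ds, c(1, 1))
  expect_warning(
    fit_timing(dup, n_sub_grid = 15, k_bounds = c(0.5, 3), network = net0),
    "degenerate")
})

test_that("measured-curve metrics survive the monitoring pipeline", {
  g <- gamma_tdc(t0 = 8, tp = 25, A = 200, dt = 0.1, horizon = 60)
  mon <- monitor_curve(g, start = 10, interval = 1)
  expect_equal(mon$time, seq(10, 60, 1))
  m <- measure_metrics(mon)
  # smoothing + 1-s sampling keep the metrics near the dense-curve values
  expect_lt(abs(m$pt - 25), 1)
  expect_lt(abs(m$pctn - 200) / 200, 0.02)
  expect_lt(abs(m$cm_at - arrival_time(g)), 0.5)
})

test_that("calibration datasets round-trip through plain files", {
  net0 <- ref_net()
  ds <- zero_noise_cohort(n = 3, seed = 13, network = net0)
  dir <- tempfile("caldata")
  write_calibration_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_calibration_dataset(dir, kappa = 25)
  expect_equal(length(back$patients), 3)
  expect_equal(back$metrics$pctn, ds$metrics$pctn, tolerance = 1e-6)
  expect_equal(vapply(back$patients, `[[`, numeric(1), "cardiac_output"),
               vapply(ds$patients, `[[`, numeric(1), "cardiac_output"),
               tolerance = 1e-6)
  expect_equal(back$curves[[2]]$enhancement, ds$curves[[2]]$enhancement,
               tolerance = 1e-6)
})
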