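test_that("sweep specs encode the two protocol families", {
  co <- sweep_spec("coronary")
  ab <- sweep_spec("abdominal")
  expect_equal(co$cm_volume, 45.5)          # 245 mg/kg x 65 kg / 350 mgI/ml
  expect_equal(ab$cm_volume, 74.3)          # 400 mg/kg x 65 kg / 350 mgI/ml
  expect_equal(co$durations, seq(8, 20, 2))
  expect_equal(ab$durations, seq(10, 40, 5))
  expect_equal(co$roi, "ascending_aorta")
  expect_equal(ab$roi, "abdominal_aorta")
  expect_equal(range(co$ci_grid), c(0.1, 6.0))
  expect_equal(diff(co$ci_grid)[1], 0.05)
  # halving the duration at fixed volume doubles the injection rate
  p1 <- injection_protocol(co$agent, co$cm_volume, duration = 16)
  p2 <- injection_protocol(co$agent, co$cm_volume, duration = 8)
  expect_equal(p2$rate, 2 * p1$rate)
  expect_error(sweep_spec("coronary", ci_grid = c(2, 1)), "increasing")
})

test_that("a small sweep is deterministic with sensible metric ordering", {
  sp <- sweep_spec("coronary", durations = 10, ci_grid = c(0.8, 1.6, 2.4, 4))
  sw1 <- run_sweep(sp, network = ref_net())
  sw2 <- run_sweep(sp, network = ref_net())
  expect_identical(sw1, sw2)
  expect_true(all(diff(sw1$cm_at) < 0))
  expect_true(all(diff(sw1$pt) < 0))
  expect_equal(nrow(sw1), 4)
  expect_length(attr(sw1, "failures"), 0)
})

test_that("window tables summarize analytic sweeps correctly", {
  ci <- seq(0.1, 6, 0.05)
  mk <- function(d, pk) data.frame(duration = d, ci = ci, cm_at = 1, pt = 2,
                                   pctn = pk)
  sweep <- rbind(mk(8, 600 - 50 * (ci - 2.5)^2),
                 mk(12, 420 - 50 * (ci - 2)^2),
                 mk(16, 340 - 50 * (ci - 1.5)^2))
  attr(sweep, "spec") <- NULL
  wt <- window_table(sweep, threshold = 350)
  expect_equal(wt$duration, c(8, 12, 16))
  expect_false(wt$ci_max_open[1])
  expect_equal(wt$width[3], 0)             # never reaches 350
  expect_true(all(diff(wt$width) <= 0))
  expect_true(attr(wt, "monotone_narrowing"))
  wt_hi <- window_table(sweep, threshold = 1e6)
  expect_true(all(wt_hi$width == 0))
  # open upper end when the curve stays above threshold at the grid edge
  sweep2 <- mk(8, rep(400, length(ci)))
  wt2 <- window_table(sweep2, threshold = 350)
  expect_true(wt2$ci_max_open)
  expect_match(wt2$label, "> 6")
})

test_that("ICC(2,1) matches its analytic anchors", {
  x <- c(3.1, 5.2, 7.4, 9.8, 12.1, 4.4, 6.6, 8.3)
  perfect <- icc_agreement(x, x)
  expect_equal(perfect$icc, 1)
  expect_true(perfect$lower <= 1 && perfect$upper >= perfect$icc - 1e-9)
  # independent noise: agreement near zero
  set.seed(100)
  a <- rnorm(300); b <- rnorm(300)
  noise <- icc_agreement(a, b)
  expect_lt(abs(noise$icc), 0.15)
  expect_true(noise$lower < noise$icc && noise$icc < noise$upper)
  # known variance ratio: subject var 4, error var 1 -> ICC = 0.8
  set.seed(101)
  subj <- rnorm(400, sd = 2)
  r <- icc_agreement(subj + rnorm(400), subj + rnorm(400))
  expect_equal(r$icc, 0.8, tolerance = 0.08)
  # a fixed offset between raters lowers absolute agreement
  off <- icc_agreement(x, x + 3)
  expect_lt(off$icc, perfect$icc)
})

test_that("cohort validation reports bins, CIs and agreement", {
  net0 <- ref_net()
  truth <- default_calibration()
  ds <- generate_cohort(cohort_spec(10, 5, seed = 51, hu_noise_sd = 0,
                                    jitter_sd = 0),
                        truth = truth, network = net0)
  vr <- validate_cohort(ds, truth, net0)
  expect_equal(levels(vr$bin), c("<=1.5", "1.6-2.0", "2.1-2.5", ">=2.6"))
  expect_equal(sum(table(vr$bin)), 10)    # bins partition the cohort
  # exact model, no noise: estimated == actual, so all ICCs are 1
  expect_true(all(abs(vr$icc$icc - 1) < 1e-6))
  expect_true(all(vr$bins$n[vr$bins$metric == "cm_at"] ==
                    as.integer(table(vr$bin))))
  # bins with fewer than 2 patients are flagged with undefined CIs
  flagged <- vr$bins[vr$bins$flagged, ]
  if (nrow(flagged))
    expect_true(all(is.na(flagged$actual_ci_lower)))
  ok <- vr$bins[!vr$bins$flagged & !is.na(vr$bins$inside), ]
  expect_true(all(ok$actual_ci_lower <= ok$actual_ci_upper))
})
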