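#' Synthetic cohort specification
#'
#' Describes a synthetic test-bolus cohort with the anthropometric structure
#' of the validation population: body weight 31.9-89.6 kg, height
#' 133.3-176.6 cm, cardiac output 1.5-6.5 l/min, sampled uniformly and
#' independently within the printed ranges (BMI clamped to 13.4-32.3 by
#' rejection). Measured curves are the simulator's own output on the 1-s
#' monitoring grid starting 10 s post-injection, degraded with additive
#' Gaussian HU noise and a Gaussian jitter on the curve start.
#'
#' @param n_patients Cohort size (default 96).
#' @param n_calibration Patients assigned to the calibration subset
#'   (default 30; the remainder is the validation subset).
#' @param seed RNG seed; a fixed seed reproduces the cohort exactly.
#' @param weight_range,height_range kg / cm sampling ranges.
#' @param co_range Cardiac output range, l/min.
#' @param bmi_range Accepted body-mass-index range (rejection sampling).
#' @param hu_noise_sd Additive HU noise standard deviation (default 10 HU).
#' @param jitter_sd Timing jitter on the curve start, s (default 0.5).
#' @param monitor_start,monitor_interval Monitoring grid, s.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 96, n_calibration = 30, seed = 1,
                        weight_range = c(31.9, 89.6),
                        height_range = c(133.3, 176.6),
                        co_range = c(1.5, 6.5),
                        bmi_range = c(13.4, 32.3),
                        hu_noise_sd = 10, jitter_sd = 0.5,
                        monitor_start = 10, monitor_interval = 1) {
  stopifnot(n_patients >= 1, n_calibration <= n_patients,
            weight_range[1] > 0, diff(weight_range) > 0,
            height_range[1] > 0, diff(height_range) > 0,
            co_range[1] > 0, diff(co_range) > 0,
            hu_noise_sd >= 0, jitter_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic test-bolus cohort
#'
#' Samples patients per the [cohort_spec()], simulates each patient's
#' ascending-aorta test-bolus curve at the ground-truth constants, resamples
#' it to the monitoring grid, applies timing jitter and HU noise, and
#' extracts both the noisy ("measured") and noiseless ("true") metrics with
#' the standard measurement pathway ([measure_metrics()]).
#'
#' @param spec A [cohort_spec()].
#' @param truth Ground-truth constants, a `calibration_result`-like list with
#'   `k_ref`, `n_sub`, `kappa` (default [default_calibration()]).
#' @param network Base network.
#' @param settings Solver settings (horizon is adapted per patient).
#' @return A [calibration_dataset()] whose extra fields carry the split and
#'   the ground truth: `calibration_idx`, `validation_idx`, `truth`,
#'   `true_metrics`, `cardiac_index` vector, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            truth = default_calibration(),
                            network = build_reference_network(),
                            settings = solver_settings(horizon = 150)) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      h <- stats::runif(1, spec$height_range[1], spec$height_range[2])
      w <- stats::runif(1, spec$weight_range[1], spec$weight_range[2])
      bmi <- w / (h / 100)^2
      if (bmi >= spec$bmi_range[1] && bmi <= spec$bmi_range[2]) break
    }
    co <- stats::runif(1, spec$co_range[1], spec$co_range[2]) * 1000
    patients[[i]] <- patient_model(h, w, cardiac_output = co)
  }
  jitter <- stats::rnorm(n, 0, spec$jitter_sd)

  proto_ds <- list(protocol = test_bolus_protocol(),
                   monitor_start = spec$monitor_start,
                   monitor_interval = spec$monitor_interval)
  curves <- vector("list", n)
  true_metrics <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- .simulated_observation(patients[[i]], proto_ds, truth$k_ref,
                                  truth$n_sub, truth$kappa, network,
                                  settings)
    true_metrics[[i]] <- sim$metrics
    # jittered start: the scanner clock sees the curve shifted by delta
    base <- sim$curve
    grid <- seq(spec$monitor_start, max(base$time), spec$monitor_interval)
    conc <- stats::approx(base$time + jitter[i], base$concentration, grid,
                          rule = 2)$y
    enh <- pmax(conc, 0) * truth$kappa +
      stats::rnorm(length(grid), 0, spec$hu_noise_sd)
    curves[[i]] <- tdc("ascending_aorta", grid, pmax(enh, 0) / truth$kappa,
                       kappa = truth$kappa)
  }
  ds <- calibration_dataset(patients, curves,
                            monitor_start = spec$monitor_start,
                            monitor_interval = spec$monitor_interval)
  ds$calibration_idx <- seq_len(spec$n_calibration)
  ds$validation_idx <- setdiff(seq_len(n), ds$calibration_idx)
  ds$truth <- truth
  ds$true_metrics <- do.call(rbind, true_metrics)
  ds$cardiac_index <- vapply(patients, `[[`, numeric(1), "cardiac_index")
  ds$spec <- spec
  ds
}

#' Subset a calibration dataset by patient index
#'
#' @param dataset A [calibration_dataset()].
#' @param idx Integer indices.
#' @return A `calibration_dataset` restricted to `idx` (split/truth fields
#'   dropped).
#' @export
subset_cohort <- function(dataset, idx) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  out <- calibration_dataset(dataset$patients[idx], dataset$curves[idx],
                             metrics = dataset$metrics[idx, , drop = FALSE],
                             protocol = dataset$protocol,
                             monitor_start = dataset$monitor_start,
                             monitor_interval = dataset$monitor_interval)
  if (!is.null(dataset$true_metrics))
    out$true_metrics <- dataset$true_metrics[idx, , drop = FALSE]
  if (!is.null(dataset$cardiac_index))
    out$cardiac_index <- dataset$cardiac_index[idx]
  out
}
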