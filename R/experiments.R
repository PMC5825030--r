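#' Cardiac-index sweep specification
#'
#' The two published protocol families for a representative 166-cm, 65.0-kg
#' subject with a 350 mgI/ml agent (osmolality 590 mOsm/kg H2O):
#' \describe{
#'   \item{coronary}{45.5 ml (245 mg iodine/kg), durations 8-20 s in 2-s
#'     steps, ROI ascending aorta.}
#'   \item{abdominal}{74.3 ml (400 mg iodine/kg), durations 10-40 s in 5-s
#'     steps, ROI abdominal aorta.}
#' }
#' The cardiac index is swept over 0.1-6.0 l/min/m^2 in steps of 0.05, and
#' 350 HU is the adequate-enhancement threshold.
#'
#' @param family `"coronary"` or `"abdominal"`.
#' @param subject A [patient_model()] preset (cardiac output is overridden at
#'   each grid point).
#' @param agent Contrast agent.
#' @param cm_volume Contrast volume, ml; default per family.
#' @param durations Injection durations, s; default per family.
#' @param ci_grid Cardiac-index grid, l/min/m^2.
#' @param roi Region of interest; default per family.
#' @param threshold Adequate-enhancement threshold, HU.
#' @return A `sweep_spec`.
#' @export
sweep_spec <- function(family = c("coronary", "abdominal"),
                       subject = representative_subject(),
                       agent = study_agent_350(),
                       cm_volume = NULL, durations = NULL, roi = NULL,
                       ci_grid = seq(0.1, 6.0, by = 0.05),
                       threshold = 350) {
  family <- match.arg(family)
  if (is.null(cm_volume))
    cm_volume <- if (family == "coronary")
      required_cm_volume(245, subject$weight, agent$iodine_concentration)
    else required_cm_volume(400, subject$weight, agent$iodine_concentration)
  if (is.null(durations))
    durations <- if (family == "coronary") seq(8, 20, by = 2)
                 else seq(10, 40, by = 5)
  if (is.null(roi))
    roi <- if (family == "coronary") "ascending_aorta" else "abdominal_aorta"
  if (any(diff(ci_grid) <= 0)) stop("ci_grid must be strictly increasing")
  if (any(durations <= 0)) stop("durations must be positive")
  structure(list(family = family, subject = subject, agent = agent,
                 cm_volume = cm_volume, durations = durations, roi = roi,
                 ci_grid = ci_grid, threshold = threshold),
            class = "sweep_spec")
}

#' Run a cardiac-index sweep
#'
#' Simulates every (injection duration, cardiac index) grid point of the
#' specification and extracts CM-AT, PT and PCTN from the ROI curve. The
#' cardiac output at each point is `CI x BSA(subject) x 1000` ml/min. The
#' simulation horizon grows as the cardiac index shrinks so the (late) peak
#' at very low output is always inside the window. Deterministic: identical
#' spec and calibration give identical tables.
#'
#' @param spec A [sweep_spec()].
#' @param calib A `calibration_result` (default [default_calibration()]).
#' @param network Base network.
#' @param settings Solver settings; horizon is adapted per grid point.
#' @param progress Print a line per duration.
#' @return data.frame: `duration`, `ci`, `cm_at`, `pt`, `pctn`. Grid points
#'   whose metric extraction fails carry `NA` and are annotated in the
#'   `failures` attribute.
#' @export
run_sweep <- function(spec, calib = default_calibration(),
                      network = build_reference_network(),
                      settings = solver_settings(), progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$durations) * length(spec$ci_grid))
  failures <- character(0)
  r <- 0L
  for (d in spec$durations) {
    prot <- injection_protocol(spec$agent, spec$cm_volume, duration = d)
    for (ci in spec$ci_grid) {
      r <- r + 1L
      pat <- patient_model(spec$subject$height, spec$subject$weight,
                           cardiac_index = ci)
      st <- settings
      st$horizon <- min(900, ceiling(d + 60 + 70 / ci))
      met <- tryCatch({
        cur <- simulate_patient(pat, prot, spec$roi, st, calib, network)
        enhancement_metrics(cur[[spec$roi]], refine = TRUE)
      }, error = function(e) {
        failures <<- c(failures,
                       sprintf("duration %g, ci %.2f: %s", d, ci,
                               conditionMessage(e)))
        data.frame(roi = spec$roi, cm_at = NA_real_, pt = NA_real_,
                   pctn = NA_real_, threshold_delta = NA, lead = NA)
      })
      rows[[r]] <- data.frame(duration = d, ci = ci, cm_at = met$cm_at,
                              pt = met$pt, pctn = met$pctn)
    }
    if (progress)
      message(sprintf("sweep %s: duration %g s done", spec$family, d))
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  attr(out, "spec") <- spec
  out
}

#' Adequate-enhancement windows per injection duration
#'
#' For each injection duration of a sweep, the cardiac-index window over
#' which the PCTN meets the threshold ([threshold_window()]), with the
#' window width. The published pattern — the window narrows (never widens)
#' as the injection duration grows — is checked and reported in the
#' `monotone_narrowing` attribute.
#'
#' @param sweep Output of [run_sweep()].
#' @param threshold HU threshold; defaults to the sweep spec's.
#' @return data.frame: `duration`, `ci_min`, `ci_max`, `ci_max_open`,
#'   `width`, `label`.
#' @export
window_table <- function(sweep, threshold = NULL) {
  spec <- attr(sweep, "spec")
  if (is.null(threshold))
    threshold <- if (!is.null(spec)) spec$threshold else 350
  durs <- unique(sweep$duration)
  rows <- lapply(durs, function(d) {
    s <- sweep[sweep$duration == d, ]
    w <- threshold_window(s$pctn, s$ci, threshold)
    width <- if (w$empty) 0 else w$ci_max - w$ci_min
    data.frame(duration = d, ci_min = w$ci_min, ci_max = w$ci_max,
               ci_max_open = w$ci_max_open, width = width, label = w$label)
  })
  out <- do.call(rbind, rows)
  attr(out, "monotone_narrowing") <-
    all(diff(out$width[order(out$duration)]) <= 1e-9)
  out
}

# ---- agreement statistics ----------------------------------------------

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two sets of measurements on the same subjects, with
#' the F-based confidence interval (McGraw & Wong conventions).
#'
#' @param x,y Paired measurements (e.g. actual and estimated metric).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `icc`, `lower`, `upper`, `n`.
#' @export
icc_agreement <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  if (mse <= 1e-300 || icc >= 1 - 1e-12) {
    # degenerate perfect agreement: the F-based interval collapses
    return(list(icc = icc, lower = icc, upper = icc, n = n))
  }
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper, n = n)
}

#' Validate the simulator against a measured cohort
#'
#' For every patient, simulates the test-bolus metrics at the calibrated
#' constants and compares them with the measured ones: per cardiac-index bin
#' (<=1.5, 1.6-2.0, 2.1-2.5, >=2.6 l/min/m^2) the mean estimated metric and
#' the Student-t 95% CI of the actual population mean, plus global ICC(2,1)
#' agreement coefficients for CM-AT, PT and PCTN.
#'
#' @param dataset A [calibration_dataset()] (typically the validation subset
#'   of a cohort).
#' @param calib A `calibration_result`.
#' @param network,settings As elsewhere.
#' @param conf_level CI level.
#' @return A `validation_report`: list with `bins` (data.frame per metric x
#'   bin: n, mean estimated, CI of actual, inside flag), `icc` (data.frame),
#'   `estimated`, `actual` (per-patient metric data.frames).
#' @export
validate_cohort <- function(dataset, calib,
                            network = build_reference_network(),
                            settings = solver_settings(horizon = 150),
                            conf_level = 0.95) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  n <- length(dataset$patients)
  est <- vector("list", n)
  for (i in seq_len(n)) {
    est[[i]] <- .simulated_observation(dataset$patients[[i]], dataset,
                                       calib$k_ref, calib$n_sub,
                                       calib$kappa, network,
                                       settings)$metrics
  }
  est <- do.call(rbind, est)
  act <- dataset$metrics
  ci_val <- vapply(dataset$patients, `[[`, numeric(1), "cardiac_index")
  bin <- cut(ci_val, c(-Inf, 1.5, 2.0, 2.5, Inf),
             labels = c("<=1.5", "1.6-2.0", "2.1-2.5", ">=2.6"))
  metrics <- c("cm_at", "pt", "pctn")
  rows <- list()
  for (m in metrics) {
    for (b in levels(bin)) {
      sel <- bin == b
      nb <- sum(sel)
      if (nb >= 2) {
        mu <- mean(act[[m]][sel]); s <- stats::sd(act[[m]][sel])
        half <- stats::qt(1 - (1 - conf_level) / 2, nb - 1) * s / sqrt(nb)
        lo <- mu - half; hi <- mu + half
      } else lo <- hi <- NA_real_
      me <- if (nb) mean(est[[m]][sel]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, bin = b, n = nb, mean_estimated = me,
        actual_ci_lower = lo, actual_ci_upper = hi,
        inside = if (nb >= 2 && !is.na(me)) me >= lo & me <= hi else NA,
        flagged = nb < 2)
    }
  }
  icc <- do.call(rbind, lapply(metrics, function(m) {
    r <- icc_agreement(act[[m]], est[[m]], conf_level)
    data.frame(metric = m, icc = r$icc, lower = r$lower, upper = r$upper)
  }))
  structure(list(bins = do.call(rbind, rows), icc = icc,
                 estimated = est, actual = act, cardiac_index = ci_val,
                 bin = bin),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report\n  ICC(2,1) agreement (95% CI):\n")
  for (i in seq_len(nrow(x$icc)))
    cat(sprintf("    %-6s %.2f (%.2f-%.2f)\n", x$icc$metric[i],
                x$icc$icc[i], x$icc$lower[i], x$icc$upper[i]))
  cat("  per-bin summary:\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}
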