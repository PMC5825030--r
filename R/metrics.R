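#' Contrast arrival time of a curve
#'
#' Arrival time (CM-AT) is defined on the time-density curve as the time at
#' which the enhancement first exceeds the unenhanced baseline by
#' `threshold_delta` HU, minus a fixed `lead` (the bolus front is taken to
#' arrive `lead` seconds before the threshold crossing). The crossing is
#' located by linear interpolation between samples; the result is clamped at
#' 0 s (with a warning) if the lead would make it negative.
#'
#' The default trigger is a 30-HU rise with a 2-s lead; a 10-HU trigger is an
#' accepted alternative convention and can be selected via `threshold_delta`.
#'
#' @param curve A [tdc()].
#' @param threshold_delta Trigger threshold above baseline, HU.
#' @param lead Lead time subtracted from the crossing, s.
#' @return Arrival time in s.
#' @export
#' @examples
#' ramp <- tdc("aorta", 0:40, pmax(0, (0:40) - 10) * 10 / 25)
#' arrival_time(ramp)  # crossing at 13 s, minus 2 -> 11 s
arrival_time <- function(curve, threshold_delta = 30, lead = 2) {
  stopifnot(inherits(curve, "tdc"))
  if (threshold_delta <= 0) stop("threshold_delta must be positive")
  rise <- curve$enhancement - curve$baseline_hu
  above <- which(rise >= threshold_delta)
  if (!length(above))
    stop("no arrival: curve never rises ", threshold_delta,
         " HU above baseline")
  i <- above[1]
  t_cross <- if (i == 1) curve$time[1] else {
    t0 <- curve$time[i - 1]; t1 <- curve$time[i]
    y0 <- rise[i - 1]; y1 <- rise[i]
    t0 + (threshold_delta - y0) / (y1 - y0) * (t1 - t0)
  }
  at <- t_cross - lead
  if (at < 0) {
    warning("arrival time clamped at 0 s (crossing at ",
            signif(t_cross, 3), " s, lead ", lead, " s)")
    at <- 0
  }
  at
}

#' Peak time and peak CT number of a curve
#'
#' Global maximum of the enhancement trace; ties are broken by the earliest
#' time. Peak time (PT) is measured from the injection start (t = 0 of the
#' curve); the peak CT number (PCTN) is the enhancement at the peak,
#' including any baseline offset.
#'
#' With `refine = TRUE` the discrete maximum is refined by fitting a
#' parabola through the three samples around it (the vertex, clamped to
#' half a sample spacing), which removes the time-grid quantization of PT —
#' useful when comparing peaks across conditions that shift the peak by less
#' than one sample.
#'
#' @param curve A [tdc()].
#' @param refine Parabolic sub-sample refinement of the peak location.
#' @return List with `pt` (s) and `pctn` (HU).
#' @export
peak <- function(curve, refine = FALSE) {
  stopifnot(inherits(curve, "tdc"))
  n <- length(curve$time)
  if (!n) stop("empty curve")
  i <- which.max(curve$enhancement)  # which.max returns the first maximum
  pt <- curve$time[i]; pctn <- curve$enhancement[i]
  if (refine && i > 1 && i < n) {
    y0 <- curve$enhancement[i - 1]; y1 <- pctn; y2 <- curve$enhancement[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) {                      # strictly concave triplet
      h <- (curve$time[i + 1] - curve$time[i - 1]) / 2
      off <- 0.5 * (y0 - y2) / denom
      off <- max(-0.5, min(0.5, off))
      pt <- pt + off * h
      pctn <- y1 - 0.25 * (y0 - y2) * off
    }
  }
  list(pt = pt, pctn = pctn)
}

#' Extract all enhancement metrics from a curve
#'
#' @inheritParams arrival_time
#' @param refine Passed to [peak()].
#' @return A one-row data.frame: `roi`, `cm_at`, `pt`, `pctn`,
#'   `threshold_delta`, `lead`.
#' @export
enhancement_metrics <- function(curve, threshold_delta = 30, lead = 2,
                                refine = FALSE) {
  pk <- peak(curve, refine = refine)
  data.frame(roi = curve$roi,
             cm_at = arrival_time(curve, threshold_delta, lead),
             pt = pk$pt, pctn = pk$pctn,
             threshold_delta = threshold_delta, lead = lead,
             stringsAsFactors = FALSE)
}

#' Cardiac-index window where the peak CT number meets a threshold
#'
#' Given peak CT numbers evaluated on a cardiac-index grid, returns the
#' smallest and largest grid cardiac index at which the PCTN is at least
#' `threshold` HU. When the PCTN never drops back below the threshold before
#' the end of the grid, the upper limit is reported as open
#' (`ci_max_open = TRUE`, printed as "> <grid max>"). If the threshold is
#' never reached, an empty window (`NA`s) is returned.
#'
#' @param pctn_by_ci Named or unnamed numeric vector of PCTN (HU); `ci` gives
#'   the grid.
#' @param ci Cardiac-index grid, strictly increasing, l/min/m^2.
#' @param threshold HU threshold for adequate enhancement (default 350).
#' @return List `ci_min`, `ci_max`, `ci_max_open` (logical), `empty`
#'   (logical), `label` (printable "min–max" string).
#' @export
threshold_window <- function(pctn_by_ci, ci, threshold = 350) {
  stopifnot(length(pctn_by_ci) == length(ci))
  if (any(diff(ci) <= 0)) stop("ci grid must be strictly increasing")
  ok <- which(pctn_by_ci >= threshold)
  if (!length(ok))
    return(list(ci_min = NA_real_, ci_max = NA_real_, ci_max_open = FALSE,
                empty = TRUE, label = "none"))
  open <- max(ok) == length(ci)
  ci_min <- ci[min(ok)]
  ci_max <- ci[max(ok)]
  list(ci_min = ci_min, ci_max = ci_max, ci_max_open = open, empty = FALSE,
       label = sprintf("%.2f %s", ci_min,
                       if (open) paste0("> ", format(max(ci), nsmall = 2))
                       else sprintf("%.2f", ci_max)))
}
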