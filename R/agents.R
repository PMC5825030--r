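#' Construct a contrast agent
#'
#' Physicochemical description of an iodinated contrast material (CM): iodine
#' concentration, osmolality relative to physiological saline, and viscosity.
#' The osmotic ratio drives the diffusion-speed scaling between agents
#' ([diffusion_coefficient()]); either the ratio itself or an absolute
#' osmolality (mOsm/kg H2O) can be supplied, the latter being divided by the
#' saline reference osmolality (290 mOsm/kg H2O by default).
#'
#' @param name Label.
#' @param iodine_concentration mgI/ml (> 0).
#' @param osmotic_ratio Osmolality relative to saline (> 0); give this or
#'   `osmolality`.
#' @param osmolality Absolute osmolality in mOsm/kg H2O; converted to a ratio
#'   using `saline_osmolality`.
#' @param viscosity mPa.s (> 0).
#' @param saline_osmolality Reference osmolality of physiological saline,
#'   mOsm/kg H2O.
#' @return An object of class `contrast_agent`.
#' @export
#' @examples
#' iopamidol_370()
#' contrast_agent("CM-350", 350, osmolality = 590, viscosity = 7.0)
contrast_agent <- function(name, iodine_concentration,
                           osmotic_ratio = NULL, osmolality = NULL,
                           viscosity, saline_osmolality = 290) {
  if (iodine_concentration <= 0) stop("iodine_concentration must be positive")
  if (viscosity <= 0) stop("viscosity must be positive")
  if (is.null(osmotic_ratio)) {
    if (is.null(osmolality)) stop("give osmotic_ratio or osmolality")
    osmotic_ratio <- osmolality / saline_osmolality
  }
  if (osmotic_ratio <= 0) stop("osmotic_ratio must be positive")
  structure(list(
    name = name,
    iodine_concentration = iodine_concentration,
    osmotic_ratio = osmotic_ratio,
    osmolality = if (is.null(osmolality)) osmotic_ratio * saline_osmolality else osmolality,
    viscosity = viscosity
  ), class = "contrast_agent")
}

#' @export
print.contrast_agent <- function(x, ...) {
  cat(sprintf("contrast_agent %s: %g mgI/ml, osmotic ratio %.2f, viscosity %.1f mPa.s\n",
              x$name, x$iodine_concentration, x$osmotic_ratio, x$viscosity))
  invisible(x)
}

#' Reference and study contrast agents
#'
#' `iopamidol_370()` is the calibration reference agent (370 mgI/ml, osmotic
#' pressure ratio to saline 2.76, viscosity 9.1 mPa.s). `study_agent_350()` is
#' the 350 mgI/ml agent of the cardiac-index sweep experiments (osmolality
#' 590 mOsm/kg H2O; viscosity comparable to commercial 350 mgI/ml agents).
#'
#' @return A `contrast_agent`.
#' @export
iopamidol_370 <- function() {
  contrast_agent("Iopamidol-370", 370, osmotic_ratio = 2.76, viscosity = 9.1)
}

#' @rdname iopamidol_370
#' @export
study_agent_350 <- function() {
  contrast_agent("CM-350", 350, osmolality = 590, viscosity = 7.0)
}

#' Contrast volume needed for a per-kilogram iodine dose
#'
#' @param iodine_dose Iodine dose in mg/kg body weight (>= 0).
#' @param weight Body weight in kg (> 0).
#' @param concentration Agent iodine concentration in mgI/ml (> 0).
#' @return Volume in ml, reported to 0.1 ml.
#' @export
#' @examples
#' required_cm_volume(245, 65.0, 350)  # 45.5 ml, coronary CTA protocol
#' required_cm_volume(400, 65.0, 350)  # 74.3 ml, abdominal CTA protocol
required_cm_volume <- function(iodine_dose, weight, concentration) {
  if (iodine_dose < 0) stop("iodine_dose must be non-negative")
  if (weight <= 0) stop("weight must be positive")
  if (concentration <= 0) stop("concentration must be positive")
  round(iodine_dose * weight / concentration, 1)
}

#' Construct an injection protocol
#'
#' A uniphasic contrast injection (constant rate over the duration) followed
#' by an optional saline flush. Exactly one of `duration` and `rate` must be
#' given; the other is derived from the contrast volume.
#'
#' @param agent A [contrast_agent()].
#' @param cm_volume Contrast volume in ml (> 0, or 0 for a null injection).
#' @param duration Injection duration in s.
#' @param rate Injection rate in ml/s.
#' @param flush_volume Saline flush volume in ml (default 20).
#' @param flush_rate Saline flush rate in ml/s; defaults to the contrast
#'   injection rate.
#' @return An object of class `injection_protocol` with both `duration` and
#'   `rate` filled in, plus `flush_duration`.
#' @export
#' @examples
#' injection_protocol(iopamidol_370(), 20, rate = 4.0)   # test bolus
#' injection_protocol(study_agent_350(), 45.5, duration = 8)
injection_protocol <- function(agent, cm_volume, duration = NULL, rate = NULL,
                               flush_volume = 20, flush_rate = NULL) {
  stopifnot(inherits(agent, "contrast_agent"))
  if (cm_volume < 0) stop("cm_volume must be non-negative")
  if (is.null(duration) == is.null(rate))
    stop("give exactly one of duration and rate")
  if (is.null(duration)) {
    if (rate <= 0) stop("rate must be positive")
    duration <- cm_volume / rate
  } else {
    if (duration <= 0) stop("duration must be positive")
    rate <- cm_volume / duration
  }
  if (flush_volume < 0) stop("flush_volume must be non-negative")
  if (is.null(flush_rate)) flush_rate <- if (rate > 0) rate else 4.0
  if (flush_rate <= 0) stop("flush_rate must be positive")
  structure(list(
    agent = agent, cm_volume = cm_volume,
    duration = duration, rate = rate,
    flush_volume = flush_volume, flush_rate = flush_rate,
    flush_duration = flush_volume / flush_rate
  ), class = "injection_protocol")
}

#' @export
print.injection_protocol <- function(x, ...) {
  cat(sprintf("injection_protocol: %.1f ml %s at %.2f ml/s over %.1f s, flush %g ml at %.1f ml/s\n",
              x$cm_volume, x$agent$name, x$rate, x$duration,
              x$flush_volume, x$flush_rate))
  invisible(x)
}

#' Iodine mass input rate of a protocol
#'
#' Rate of iodine delivery at time `t` (s from injection start): constant
#' `rate * iodine_concentration` while contrast is being injected, zero during
#' the saline flush and afterwards. The companion volumetric rate (contrast or
#' saline volume per second entering the injection-site vein, used to boost
#' venous washout during injection and flush) is returned by
#' `injection_volume_rate()`.
#'
#' @param protocol An [injection_protocol()].
#' @param t Time in s (vectorized, >= 0).
#' @return Iodine mass rate in mg/s.
#' @export
injection_input <- function(protocol, t) {
  stopifnot(inherits(protocol, "injection_protocol"))
  if (any(t < 0)) stop("t must be non-negative")
  ifelse(t < protocol$duration & protocol$cm_volume > 0,
         protocol$rate * protocol$agent$iodine_concentration, 0)
}

#' @rdname injection_input
#' @return `injection_volume_rate()`: volumetric rate in ml/s.
#' @export
injection_volume_rate <- function(protocol, t) {
  stopifnot(inherits(protocol, "injection_protocol"))
  if (any(t < 0)) stop("t must be non-negative")
  d <- protocol$duration
  ifelse(t < d & protocol$cm_volume > 0, protocol$rate,
         ifelse(t >= d & t < d + protocol$flush_duration, protocol$flush_rate, 0))
}
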