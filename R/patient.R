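#' Estimate cardiac output from height and weight
#'
#' Allometric power-law estimate of resting cardiac output,
#' \eqn{CO = 25.3 \, H^{0.725} \, W^{0.425}} ml/min with height in cm and
#' weight in kg. Used whenever a patient record carries no measured cardiac
#' output. The exponents are those of the DuBois body-surface-area formula, so
#' the estimated cardiac index is the same (about 3.52 l/min/m^2) for every
#' body size.
#'
#' @param height Height in cm (> 0).
#' @param weight Weight in kg (> 0).
#' @return Cardiac output in ml/min.
#' @seealso [body_surface_area()]
#' @export
#' @examples
#' estimate_cardiac_output(170, 60)
estimate_cardiac_output <- function(height, weight) {
  stopifnot(is.numeric(height), is.numeric(weight))
  if (any(height <= 0) || any(weight <= 0))
    stop("height and weight must be positive")
  25.3 * height^0.725 * weight^0.425
}

#' Body surface area (DuBois)
#'
#' DuBois formula \eqn{BSA = 0.007184 \, H^{0.725} \, W^{0.425}} m^2,
#' height in cm, weight in kg.
#'
#' @inheritParams estimate_cardiac_output
#' @return Body surface area in m^2.
#' @export
body_surface_area <- function(height, weight) {
  stopifnot(is.numeric(height), is.numeric(weight))
  if (any(height <= 0) || any(weight <= 0))
    stop("height and weight must be positive")
  0.007184 * height^0.725 * weight^0.425
}

#' Construct a patient model
#'
#' Bundles the anthropometrics and circulatory state of one simulated subject.
#' Cardiac output may be given directly (ml/min), via the cardiac index
#' (l/min/m^2), or left out, in which case it is estimated from height and
#' weight with [estimate_cardiac_output()].
#'
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @param cardiac_output Measured cardiac output in ml/min, or `NULL`.
#' @param cardiac_index Cardiac index in l/min/m^2, or `NULL`. At most one of
#'   `cardiac_output` and `cardiac_index` may be given.
#' @param pulse_rate Pulse rate in beats/min; carried for bookkeeping, unused
#'   by the transport model.
#' @return An object of class `patient_model` with fields `height`, `weight`,
#'   `cardiac_output` (ml/min), `body_surface_area` (m^2), `cardiac_index`
#'   (l/min/m^2), `pulse_rate`, and `co_estimated` (logical).
#' @export
#' @examples
#' patient_model(166, 65)                       # CO estimated
#' patient_model(166, 65, cardiac_index = 2.1)  # CO from cardiac index
patient_model <- function(height, weight, cardiac_output = NULL,
                          cardiac_index = NULL, pulse_rate = NA_real_) {
  if (height <= 0 || weight <= 0)
    stop("height and weight must be positive")
  if (!is.null(cardiac_output) && !is.null(cardiac_index))
    stop("give at most one of cardiac_output and cardiac_index")
  bsa <- body_surface_area(height, weight)
  estimated <- FALSE
  if (!is.null(cardiac_index)) {
    if (cardiac_index <= 0) stop("cardiac_index must be positive")
    cardiac_output <- cardiac_index * bsa * 1000
  } else if (is.null(cardiac_output)) {
    cardiac_output <- estimate_cardiac_output(height, weight)
    estimated <- TRUE
  }
  if (cardiac_output <= 0) stop("cardiac_output must be positive")
  structure(list(
    height = height, weight = weight,
    cardiac_output = cardiac_output,
    body_surface_area = bsa,
    cardiac_index = cardiac_output / bsa / 1000,
    pulse_rate = pulse_rate,
    co_estimated = estimated
  ), class = "patient_model")
}

#' @export
print.patient_model <- function(x, ...) {
  cat(sprintf("patient_model: %.1f cm, %.1f kg, BSA %.2f m^2\n",
              x$height, x$weight, x$body_surface_area))
  cat(sprintf("  cardiac output %.0f ml/min (%s), cardiac index %.2f l/min/m^2\n",
              x$cardiac_output, if (x$co_estimated) "estimated" else "given",
              x$cardiac_index))
  invisible(x)
}

#' Named subject presets
#'
#' `reference_subject()` is the 60-kg, 1.7-m adult male the reference
#' compartment table describes. `representative_subject()` is the 166-cm,
#' 65.0-kg subject used by the cardiac-index sweep experiments.
#'
#' @param ... Passed on to [patient_model()] (e.g. `cardiac_index = `).
#' @return A `patient_model`.
#' @export
reference_subject <- function(...) patient_model(170, 60, ...)

#' @rdname reference_subject
#' @export
representative_subject <- function(...) patient_model(166, 65.0, ...)
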