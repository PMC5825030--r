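#' Solver settings
#'
#' @param dt Output time step in s.
#' @param horizon Simulation horizon in s.
#' @param integrator `"rk4"` (fixed-step, deterministic). When
#'   `auto_substep` is `TRUE` each output step is internally subdivided so
#'   that the step stays within the RK4 stability bound of the system's
#'   spectral norm; the output grid is unchanged.
#' @param hu_per_mgi_ml Conversion coefficient kappa between iodine
#'   concentration (mgI/ml) and CT enhancement (HU); about 25 HU.ml/mgI at
#'   120 kVp until calibrated.
#' @param baseline_hu Unenhanced CT number added to curves.
#' @param readout ROI concentration readout: `"mean"` (whole-compartment
#'   intravascular mass / V_iv) or `"outlet"` (last sub-compartment).
#' @param auto_substep Automatically subdivide unstable steps (default). If
#'   `FALSE`, an unstable step size raises an error.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(dt = 0.1, horizon = 180, integrator = "rk4",
                            hu_per_mgi_ml = 25, baseline_hu = 0,
                            readout = c("mean", "outlet"),
                            auto_substep = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  if (horizon <= dt) stop("horizon must exceed dt")
  if (hu_per_mgi_ml <= 0) stop("hu_per_mgi_ml must be positive")
  readout <- match.arg(readout)
  structure(list(dt = dt, horizon = horizon, integrator = integrator,
                 hu_per_mgi_ml = hu_per_mgi_ml, baseline_hu = baseline_hu,
                 readout = readout, auto_substep = auto_substep),
            class = "solver_settings")
}

#' Scale the reference diffusion speed to another agent
#'
#' The in-blood diffusion speed of a contrast agent is taken proportional to
#' its osmotic pressure ratio to saline and (optionally) inversely
#' proportional to its viscosity, relative to the calibrated reference agent:
#' `k = k_ref * (osm_agent / osm_ref)` in `"osmotic"` mode (the default,
#' matching how agents other than the reference are handled), with an extra
#' factor `visc_ref / visc_agent` in `"osmotic_viscosity"` mode.
#'
#' @param agent Target [contrast_agent()].
#' @param reference Reference agent the calibration used (default
#'   [iopamidol_370()]).
#' @param k_ref Calibrated diffusion speed of the reference agent, 1/s.
#' @param mode `"osmotic"` or `"osmotic_viscosity"`.
#' @return Diffusion speed in 1/s.
#' @export
diffusion_coefficient <- function(agent, reference = iopamidol_370(), k_ref,
                                  mode = c("osmotic", "osmotic_viscosity")) {
  stopifnot(inherits(agent, "contrast_agent"),
            inherits(reference, "contrast_agent"))
  if (k_ref <= 0) stop("k_ref must be positive")
  mode <- match.arg(mode)
  k <- k_ref * agent$osmotic_ratio / reference$osmotic_ratio
  if (mode == "osmotic_viscosity") {
    if (agent$viscosity <= 0) stop("viscosity must be positive")
    k <- k * reference$viscosity / agent$viscosity
  }
  k
}

# ---- system assembly ----------------------------------------------------

# Build the sparse linear transport operator for a network.
# State layout: per compartment, n_sub intravascular sub-unit masses (mg);
# then one extracellular mass per compartment with v_ec > 0; then the
# syringe reservoir as the final state. All rates per second.
build_transport_system <- function(network, n_sub = NULL) {
  comp <- network$compartments
  if (any(comp$v_iv <= 0))
    stop("all compartments need positive intravascular volume")
  C <- nrow(comp)
  K <- if (is.null(n_sub)) as.integer(comp$n_sub) else rep(as.integer(n_sub), C)
  if (any(K < 1)) stop("n_sub must be >= 1")
  offset <- cumsum(c(0L, K))[seq_len(C)]
  n_iv <- sum(K)
  has_ec <- comp$v_ec > 0 & comp$k_tc > 0
  ec_index <- integer(C)
  ec_index[has_ec] <- n_iv + seq_len(sum(has_ec))
  n_state <- n_iv + sum(has_ec) + 1L
  syr_index <- n_state

  ti <- tj <- integer(0); tx <- numeric(0)
  add <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x)
  }
  cid <- stats::setNames(seq_len(C), comp$name)

  for (c in seq_len(C)) {
    k <- K[c]; idx <- offset[c] + seq_len(k)
    Q <- comp$blood_flow[c] / 60          # ml/s
    lam <- Q * k / comp$v_iv[c]           # 1/s per sub-unit
    add(idx, idx, rep(-lam, k))
    if (k > 1) add(idx[-1], idx[-k], rep(lam, k - 1))
    # transcapillary exchange with the extracellular pool
    if (has_ec[c]) {
      r <- comp$k_tc[c] / 60
      ratio <- comp$v_ec[c] / comp$v_iv[c]
      e <- ec_index[c]
      add(idx, idx, rep(-r * ratio, k))
      add(rep(e, k), idx, rep(r * ratio, k))
      add(idx, rep(e, k), rep(r / k, k))
      add(rep(e, k), rep(e, k), rep(-r / k, k))
    }
  }
  # inter-compartment advection: edge flow carries the source outlet
  # concentration into the destination inlet sub-unit
  for (e in seq_len(nrow(network$edges))) {
    s <- cid[[network$edges$from[e]]]; d <- cid[[network$edges$to[e]]]
    qe <- network$edges$flow[e] / 60
    add(offset[d] + 1L, offset[s] + K[s], qe * K[s] / comp$v_iv[s])
  }

  # diffusion Laplacian (unit coefficient) between adjacent sub-units
  di <- dj <- integer(0); dx <- numeric(0)
  for (c in seq_len(C)) {
    k <- K[c]
    if (k < 2) next
    idx <- offset[c] + seq_len(k)
    a <- idx[-k]; b <- idx[-1]
    di <- c(di, a, a, b, b); dj <- c(dj, b, a, a, b)
    dx <- c(dx, rep(1, k - 1), rep(-1, k - 1), rep(1, k - 1), rep(-1, k - 1))
  }

  # extra advection through the injection-site compartment per unit ml/s
  v <- cid[[network$injection_site]]
  if (is.null(v)) stop("injection site '", network$injection_site,
                       "' not in network")
  k <- K[v]; idx <- offset[v] + seq_len(k)
  lam_u <- k / comp$v_iv[v]
  vi <- idx; vj <- idx; vx <- rep(-lam_u, k)
  if (k > 1) { vi <- c(vi, idx[-1]); vj <- c(vj, idx[-k]); vx <- c(vx, rep(lam_u, k - 1)) }
  oute <- which(network$edges$from == comp$name[v])
  fr <- network$edges$flow[oute] / sum(network$edges$flow[oute])
  for (m in seq_along(oute)) {
    d <- cid[[network$edges$to[oute[m]]]]
    vi <- c(vi, offset[d] + 1L); vj <- c(vj, offset[v] + k)
    vx <- c(vx, fr[m] * k / comp$v_iv[v])
  }

  list(n_state = n_state, offset = offset, K = K,
       names = comp$name, v_iv = comp$v_iv, v_ec = comp$v_ec,
       ec_index = ec_index, syr_index = syr_index,
       inj_index = offset[v] + 1L,
       A = list(i = ti, j = tj, x = tx),
       D = list(i = di, j = dj, x = dx),
       V = list(i = vi, j = vj, x = vx))
}

# induced 1-norm bound of A + k*D + u*V from triplets
.system_norm <- function(sys, k_diff, u_max) {
  n <- sys$n_state
  cs <- numeric(n)
  acc <- function(tr, w) {
    if (length(tr$j)) {
      s <- tapply(abs(tr$x) * w, tr$j, sum)
      cs[as.integer(names(s))] <<- cs[as.integer(names(s))] + as.numeric(s)
    }
  }
  acc(sys$A, 1); acc(sys$D, k_diff); acc(sys$V, u_max)
  max(cs)
}

# Dense derivative evaluation (reference implementation used by tests).
# state: full state vector; returns d(state)/dt at time t.
transport_derivatives <- function(sys, state, t, protocol = NULL,
                                  k_diff = 0) {
  stopifnot(length(state) == sys$n_state)
  if (any(state < 0)) stop("integrity error: negative mass in state")
  y <- numeric(sys$n_state)
  sp <- function(tr, w) {
    if (length(tr$i))
      for (k in seq_along(tr$i))
        y[tr$i[k]] <<- y[tr$i[k]] + w * tr$x[k] * state[tr$j[k]]
  }
  sp(sys$A, 1)
  if (k_diff > 0) sp(sys$D, k_diff)
  if (!is.null(protocol)) {
    u <- injection_volume_rate(protocol, t)
    if (u > 0) sp(sys$V, u)
    s <- injection_input(protocol, t)
    y[sys$inj_index] <- y[sys$inj_index] + s
    y[sys$syr_index] <- y[sys$syr_index] - s
  }
  y
}

# ---- integration --------------------------------------------------------

#' Run the iodine transport simulation on a network
#'
#' Low-level entry point: integrates the full mass-transport system for a
#' given (already scaled/adjusted) network and injection protocol and returns
#' the complete state trajectory. Most users want [simulate_patient()].
#'
#' @param network A `pbpk_network`, already scaled to the subject.
#' @param protocol An [injection_protocol()]; `NULL` for source-free runs.
#' @param settings [solver_settings()].
#' @param k_diff In-blood diffusion speed (1/s) between adjacent sub-units.
#' @param n_sub Optional global override of the per-compartment
#'   sub-compartment count.
#' @param init Optional named list of initial masses,
#'   `list(c(compartment, sub) = mg, ...)` given as a data.frame with columns
#'   `compartment`, `sub`, `mass`; used by the impulse-response tests.
#' @return A `transport_run`: list with `time` (s), `states` (matrix,
#'   state x time), `sys` (layout), `mass_error` (worst relative deviation of
#'   total mass from its initial value), `worst_negative`.
#' @export
run_transport <- function(network, protocol, settings = solver_settings(),
                          k_diff = 0, n_sub = NULL, init = NULL) {
  sys <- build_transport_system(network, n_sub = n_sub)
  state0 <- numeric(sys$n_state)
  if (!is.null(init)) {
    for (r in seq_len(nrow(init))) {
      c <- match(init$compartment[r], sys$names)
      if (is.na(c)) stop("unknown compartment '", init$compartment[r], "'")
      state0[sys$offset[c] + init$sub[r]] <- init$mass[r]
    }
  }
  if (is.null(protocol)) {
    mdot <- 0; d <- 0; r1 <- 0; fd <- 0; r2 <- 0
  } else {
    mdot <- if (protocol$duration > 0)
      protocol$cm_volume * protocol$agent$iodine_concentration / protocol$duration
    else 0
    d <- protocol$duration; r1 <- protocol$rate
    fd <- protocol$flush_duration; r2 <- protocol$flush_rate
    state0[sys$syr_index] <- protocol$cm_volume * protocol$agent$iodine_concentration
  }
  n_steps <- ceiling(settings$horizon / settings$dt)
  u_max <- max(r1, r2)
  nrm <- .system_norm(sys, k_diff, u_max)
  substeps <- max(1L, as.integer(ceiling(settings$dt * nrm / 2.0)))
  if (substeps > 1 && !settings$auto_substep)
    stop("unstable integration: dt = ", settings$dt,
         " exceeds the stability bound; use dt <= ",
         signif(2.0 / nrm, 3), " s or auto_substep = TRUE")

  res <- .rk4_transport(sys$n_state,
                        sys$A$i - 1L, sys$A$j - 1L, sys$A$x,
                        sys$D$i - 1L, sys$D$j - 1L, sys$D$x,
                        sys$V$i - 1L, sys$V$j - 1L, sys$V$x,
                        k_diff,
                        sys$inj_index - 1L, sys$syr_index - 1L,
                        mdot, d, r1, fd, r2,
                        state0, settings$dt, as.integer(n_steps),
                        substeps, seq_len(sys$n_state) - 1L)
  total0 <- sum(state0)
  totals <- colSums(res$states)
  mass_error <- if (total0 > 0) max(abs(totals - total0)) / total0 else 0
  if (total0 > 0 && res$worst_negative < -1e-8 * total0)
    stop("unstable integration: negative masses encountered; reduce dt")
  structure(list(time = seq(0, by = settings$dt, length.out = n_steps + 1),
                 states = res$states, sys = sys,
                 total0 = total0, mass_error = mass_error,
                 worst_negative = res$worst_negative,
                 substeps = substeps),
            class = "transport_run")
}

#' @export
print.transport_run <- function(x, ...) {
  cat(sprintf("transport_run: %d states, %d steps (x%d substeps), mass error %.2e\n",
              nrow(x$states), length(x$time) - 1, x$substeps, x$mass_error))
  invisible(x)
}

#' Concentration trace of one compartment from a transport run
#'
#' @param run A `transport_run`.
#' @param compartment Compartment name.
#' @param readout `"mean"` (total intravascular mass / V_iv) or `"outlet"`
#'   (last sub-unit mass / sub-unit volume).
#' @return Numeric vector, mgI/ml on the run's time grid.
#' @export
compartment_concentration <- function(run, compartment,
                                      readout = c("mean", "outlet")) {
  readout <- match.arg(readout)
  sys <- run$sys
  c <- match(compartment, sys$names)
  if (is.na(c)) stop("unknown compartment '", compartment, "'")
  idx <- sys$offset[c] + seq_len(sys$K[c])
  if (readout == "mean") {
    colSums(run$states[idx, , drop = FALSE]) / sys$v_iv[c]
  } else {
    run$states[idx[length(idx)], ] / (sys$v_iv[c] / sys$K[c])
  }
}

# ---- time-density curves ------------------------------------------------

#' Time-density curve
#'
#' Container for one region of interest's iodine-concentration and
#' enhancement trace. `enhancement = kappa * concentration + baseline_hu`.
#'
#' @param roi ROI label.
#' @param time Time grid, s.
#' @param concentration mgI/ml, same length as `time`, non-negative.
#' @param kappa HU.ml/mgI conversion coefficient.
#' @param baseline_hu Unenhanced CT number.
#' @return A `tdc` object (also a data.frame via [as.data.frame.tdc()]).
#' @export
tdc <- function(roi, time, concentration, kappa = 25, baseline_hu = 0) {
  stopifnot(length(time) == length(concentration))
  if (any(concentration < 0)) stop("concentration must be non-negative")
  if (kappa <= 0) stop("kappa must be positive")
  structure(list(roi = roi, time = time, concentration = concentration,
                 enhancement = kappa * concentration + baseline_hu,
                 kappa = kappa, baseline_hu = baseline_hu),
            class = "tdc")
}

#' @export
as.data.frame.tdc <- function(x, ...) {
  data.frame(roi = x$roi, time = x$time, concentration = x$concentration,
             enhancement = x$enhancement)
}

#' @export
print.tdc <- function(x, ...) {
  cat(sprintf("tdc[%s]: %d samples over %.1f s, peak %.1f HU\n",
              x$roi, length(x$time), max(x$time), max(x$enhancement)))
  invisible(x)
}

#' @export
plot.tdc <- function(x, ...) {
  graphics::plot(x$time, x$enhancement, type = "l", xlab = "time (s)",
                 ylab = "enhancement (HU)", main = x$roi, ...)
  invisible(x)
}

#' Re-express a curve in Hounsfield units
#'
#' @param curve A [tdc()].
#' @param kappa HU.ml/mgI conversion coefficient (> 0).
#' @param baseline_hu Unenhanced CT number offset.
#' @return A new `tdc` with updated enhancement.
#' @export
to_hounsfield <- function(curve, kappa, baseline_hu = 0) {
  stopifnot(inherits(curve, "tdc"))
  tdc(curve$roi, curve$time, curve$concentration, kappa, baseline_hu)
}

#' Calibration constants
#'
#' Bundle of the simulator's free constants: the reference-agent diffusion
#' speed `k_ref` (1/s), the global sub-compartment count `n_sub`, and the
#' HU conversion coefficient `kappa` (HU.ml/mgI). The defaults are the
#' package's reference calibration (see the methods vignette); refit against
#' measured curves with [calibrate()].
#'
#' @param k_ref Diffusion speed of the reference agent, 1/s.
#' @param n_sub Sub-compartments per organ/vessel compartment.
#' @param kappa HU.ml/mgI at the calibrated tube voltage.
#' @param diffusion_mode Agent scaling mode for [diffusion_coefficient()].
#' @return A `calibration_result`-like list.
#' @export
default_calibration <- function(k_ref = 1.2, n_sub = 15, kappa = 25,
                                diffusion_mode = "osmotic") {
  structure(list(k_ref = k_ref, n_sub = as.integer(n_sub), kappa = kappa,
                 diffusion_mode = diffusion_mode,
                 objective_value = NA_real_, residuals = NULL),
            class = "calibration_result")
}

#' Simulate time-density curves for a patient
#'
#' High-level simulation: scales the reference network to the patient, runs
#' the transport solver under the injection protocol, and extracts one
#' time-density curve per requested region of interest.
#'
#' @param patient A [patient_model()].
#' @param protocol An [injection_protocol()].
#' @param rois Character vector of ROI labels (see the network `roi_map`;
#'   compartment names are accepted directly).
#' @param settings [solver_settings()].
#' @param calibration A `calibration_result` (defaults to
#'   [default_calibration()]); supplies `k_ref`, `n_sub` and `kappa`.
#' @param network Base network, defaults to [build_reference_network()].
#' @return Named list of [tdc()] curves, one per ROI, with attributes
#'   `mass_error` (relative) and `run` settings.
#' @export
#' @examples
#' \donttest{
#' pat <- representative_subject(cardiac_index = 2.5)
#' prot <- injection_protocol(study_agent_350(), 45.5, duration = 8)
#' curves <- simulate_patient(pat, prot, "ascending_aorta",
#'                            solver_settings(horizon = 60))
#' max(curves$ascending_aorta$enhancement)
#' }
simulate_patient <- function(patient, protocol, rois = "ascending_aorta",
                             settings = solver_settings(),
                             calibration = default_calibration(),
                             network = build_reference_network()) {
  stopifnot(inherits(patient, "patient_model"),
            inherits(protocol, "injection_protocol"))
  net <- patient_network(patient, network)
  comps <- vapply(rois, function(r) {
    if (r %in% names(net$roi_map)) net$roi_map[[r]]
    else if (r %in% net$compartments$name) r
    else stop("unknown ROI '", r, "'")
  }, character(1))
  k_diff <- diffusion_coefficient(protocol$agent, iopamidol_370(),
                                  calibration$k_ref,
                                  mode = calibration$diffusion_mode)
  run <- run_transport(net, protocol, settings, k_diff = k_diff,
                       n_sub = calibration$n_sub)
  curves <- lapply(seq_along(rois), function(i) {
    conc <- compartment_concentration(run, comps[i], settings$readout)
    tdc(rois[i], run$time, conc, kappa = calibration$kappa,
        baseline_hu = settings$baseline_hu)
  })
  names(curves) <- rois
  attr(curves, "mass_error") <- run$mass_error
  attr(curves, "substeps") <- run$substeps
  curves
}

#' Write time-density curves as tabular text
#'
#' One tab-separated file per ROI (time s, concentration mgI/ml,
#' enhancement HU) plus a JSON metadata bundle.
#'
#' @param curves Result of [simulate_patient()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param meta Optional list of metadata stored alongside.
#' @return Invisibly, the written file paths.
#' @export
write_curves <- function(curves, dir, prefix = "curve", meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(curves)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
    utils::write.table(as.data.frame(curves[[nm]])[c("time", "concentration",
                                                     "enhancement")],
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(c(meta, list(rois = names(curves))), mp,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
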