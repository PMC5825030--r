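# Shared fixtures, built in code.

# Single-pass "tube" network: one tanks-in-series compartment fed from a very
# large reservoir, so recirculation is negligible over the test horizon.
# Used for impulse-response (Erlang / exponential washout) oracles.
tube_network <- function(q_ml_min = 300, v_tube = 75, k_tube = 15,
                         v_res = 1e9) {
  comp <- data.frame(
    name = c("reservoir", "tube"),
    blood_flow = c(q_ml_min, q_ml_min),
    v_iv = c(v_res, v_tube),
    v_ec = c(0, 0),
    n_sub = c(1L, k_tube),
    k_tc = c(0, 0))
  edges <- data.frame(from = c("reservoir", "tube"),
                      to = c("tube", "reservoir"),
                      flow = c(q_ml_min, q_ml_min))
  structure(list(compartments = comp, edges = edges,
                 injection_site = "reservoir",
                 roi_map = c(tube = "tube"), weight = 60),
            class = "pbpk_network")
}

# Impulse response of the tube: unit mass in sub-compartment 1 at t = 0,
# returns time grid and the outlet mass-rate density (1/s).
tube_impulse <- function(net, dt = 0.01, horizon = 60) {
  run <- run_transport(net, protocol = NULL,
                       settings = solver_settings(dt = dt, horizon = horizon),
                       init = data.frame(compartment = "tube", sub = 1,
                                         mass = 1))
  k <- run$sys$K[2]
  v_sub <- run$sys$v_iv[2] / k
  q <- net$compartments$blood_flow[2] / 60
  outlet_idx <- run$sys$offset[2] + k
  list(time = run$time, density = run$states[outlet_idx, ] * q / v_sub,
       run = run)
}

# Gamma-variate enhancement curve with analytic peak (pt = tp, pctn = A).
gamma_tdc <- function(t0 = 5, tp = 22, alpha = 3, A = 300, dt = 0.1,
                      horizon = 80, baseline = 0, kappa = 25) {
  tt <- seq(0, horizon, by = dt)
  y <- ifelse(tt <= t0, 0,
              A * ((tt - t0) / (tp - t0))^alpha *
                exp(alpha * (1 - (tt - t0) / (tp - t0))))
  tdc("synthetic", tt, y / kappa, kappa = kappa, baseline_hu = baseline)
}

# Small deterministic zero-noise cohort for calibration self-consistency.
zero_noise_cohort <- function(n = 4, seed = 7, truth = default_calibration(),
                              network = ref_net()) {
  generate_cohort(cohort_spec(n_patients = n, n_calibration = n, seed = seed,
                              hu_noise_sd = 0, jitter_sd = 0),
                  truth = truth, network = network)
}

# Reference network built once per test session.
ref_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_reference_network()
    net
  }
})
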