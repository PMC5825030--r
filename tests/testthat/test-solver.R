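test_that("injection input delivers iodine during contrast, volume during flush", {
  prot <- injection_protocol(study_agent_350(), 45.5, duration = 8,
                             flush_volume = 20)
  # constant mass rate while contrast runs: (45.5/8) ml/s x 350 mgI/ml
  expect_equal(injection_input(prot, 4), 45.5 / 8 * 350)
  expect_equal(injection_input(prot, 8), 0)        # flush carries no iodine
  expect_equal(injection_input(prot, 100), 0)
  # time-integral of the mass rate equals the injected iodine mass
  tt <- seq(0, 30, by = 1e-3)
  expect_equal(sum(injection_input(prot, tt)) * 1e-3, 45.5 * 350,
               tolerance = 1e-3)
  # volumetric rate covers contrast then flush at their own rates
  expect_equal(injection_volume_rate(prot, 4), 45.5 / 8)
  expect_equal(injection_volume_rate(prot, 9), 45.5 / 8)  # flush at cm rate
  expect_equal(injection_volume_rate(prot, 8 + 20 / (45.5 / 8) + 0.01), 0)
  expect_error(injection_protocol(study_agent_350(), 10, duration = 2,
                                  rate = 5), "exactly one")
})

test_that("diffusion speed scales with osmotic ratio (and optionally viscosity)", {
  ref <- iopamidol_370()
  expect_equal(diffusion_coefficient(ref, ref, k_ref = 0.8), 0.8)
  doubled <- contrast_agent("x", 300, osmotic_ratio = 2 * ref$osmotic_ratio,
                            viscosity = ref$viscosity)
  expect_equal(diffusion_coefficient(doubled, ref, 0.8), 1.6)
  # the 350 mgI/ml study agent: osmolality 590 vs saline 290
  a350 <- study_agent_350()
  expect_equal(diffusion_coefficient(a350, ref, 1.2),
               1.2 * (590 / 290) / 2.76)
  expect_equal(diffusion_coefficient(a350, ref, 1.2,
                                     mode = "osmotic_viscosity"),
               1.2 * (590 / 290) / 2.76 * 9.1 / a350$viscosity)
  expect_error(diffusion_coefficient(a350, ref, -1), "positive")
})

test_that("single well-mixed tank washes out exponentially", {
  net <- tube_network(q_ml_min = 300, v_tube = 100, k_tube = 1)
  imp <- tube_impulse(net, dt = 0.01, horizon = 40)
  run <- imp$run
  m_tube <- run$states[run$sys$offset[2] + 1, ]
  lam <- 300 / 60 / 100
  exact <- exp(-lam * run$time)
  expect_lt(max(abs(m_tube - exact)), 1e-6)
  keep <- exact > 1e-3
  expect_lt(max(abs(m_tube[keep] / exact[keep] - 1)), 1e-3)
})

test_that("tanks-in-series impulse response is the Erlang density", {
  k <- 15
  net <- tube_network(q_ml_min = 300, v_tube = 75, k_tube = k)
  imp <- tube_impulse(net, dt = 0.01, horizon = 60)
  rate <- k * (300 / 60) / 75            # K * Q / V = 1 per s
  exact <- stats::dgamma(imp$time, shape = k, rate = rate)
  l1 <- sum(abs(imp$density - exact)) * 0.01
  expect_lt(l1, 0.01)
  # peak location: mode of Erlang(15, 1) at (k-1)/rate = 14 s
  expect_equal(imp$time[which.max(imp$density)], 14, tolerance = 0.02)
})

test_that("mass is conserved and masses stay non-negative across regimes", {
  net0 <- ref_net()
  for (ci in c(0.3, 2.5, 6)) {
    for (dur in c(5, 20)) {
      pat <- patient_model(166, 65, cardiac_index = ci)
      prot <- injection_protocol(study_agent_350(), 45.5, duration = dur)
      run <- run_transport(patient_network(pat, net0), prot,
                           solver_settings(horizon = 120), k_diff = 0.9,
                           n_sub = 15)
      expect_lt(run$mass_error, 1e-6)
      expect_true(all(run$states >= 0))
      expect_gt(run$worst_negative, -1e-8 * run$total0)
    }
  }
  # flush-free protocol conserves too
  prot0 <- injection_protocol(iopamidol_370(), 20, rate = 4, flush_volume = 0)
  run <- run_transport(net0, prot0, solver_settings(horizon = 90),
                       k_diff = 1.2, n_sub = 15)
  expect_lt(run$mass_error, 1e-6)
})

test_that("derivatives conserve mass and reject invalid state", {
  net <- ref_net()
  sys <- ctbolus:::build_transport_system(net, n_sub = 5)
  prot <- test_bolus_protocol()
  z <- numeric(sys$n_state)
  expect_equal(ctbolus:::transport_derivatives(sys, z, 0), z)
  # during injection the only net mass change is syringe -> inlet (sums to 0)
  st <- z; st[sys$syr_index] <- 7400; st[sys$inj_index] <- 5
  d <- ctbolus:::transport_derivatives(sys, st, 1, prot, k_diff = 1)
  expect_equal(sum(d), 0, tolerance = 1e-12)
  expect_lt(d[sys$syr_index], 0)
  st_bad <- z; st_bad[1] <- -1
  expect_error(ctbolus:::transport_derivatives(sys, st_bad, 0), "integrity")
})

test_that("solver converges in dt and flags genuinely unstable settings", {
  pat <- patient_model(166, 65, cardiac_index = 2.5)
  prot <- injection_protocol(study_agent_350(), 45.5, duration = 8)
  st1 <- solver_settings(dt = 0.1, horizon = 90)
  st2 <- solver_settings(dt = 0.05, horizon = 90)
  c1 <- simulate_patient(pat, prot, "ascending_aorta", st1, network = ref_net())
  c2 <- simulate_patient(pat, prot, "ascending_aorta", st2, network = ref_net())
  expect_lt(abs(peak(c1$ascending_aorta)$pctn -
                  peak(c2$ascending_aorta)$pctn), 0.5)
  expect_error(
    run_transport(patient_network(pat, ref_net()), prot,
                  solver_settings(dt = 0.5, horizon = 10,
                                  auto_substep = FALSE),
                  k_diff = 1, n_sub = 15),
    "unstable")
})

test_that("zero contrast volume yields flat zero curves", {
  pat <- patient_model(166, 65, cardiac_index = 2.5)
  prot <- injection_protocol(study_agent_350(), 0, duration = 8)
  cur <- simulate_patient(pat, prot, c("ascending_aorta", "abdominal_aorta"),
                          solver_settings(horizon = 30), network = ref_net())
  expect_true(all(cur$ascending_aorta$concentration == 0))
  expect_true(all(cur$abdominal_aorta$enhancement == 0))
})

test_that("enhancement conversion is linear in kappa with baseline offset", {
  cu <- tdc("x", 0:10, c(0:9, 14), kappa = 25)
  expect_equal(max(cu$enhancement), 350)
  zero <- tdc("x", 0:5, rep(0, 6), kappa = 25, baseline_hu = 40)
  expect_true(all(zero$enhancement == 40))
  h2 <- to_hounsfield(cu, 50)
  expect_equal(h2$enhancement - h2$baseline_hu,
               2 * (cu$enhancement - cu$baseline_hu))
  expect_error(to_hounsfield(cu, 0), "positive")
  expect_error(tdc("x", 0:2, c(-1, 0, 1)), "non-negative")
})

test_that("faster circulation strictly shortens aortic arrival time", {
  net0 <- ref_net()
  prot <- injection_protocol(study_agent_350(), 45.5, duration = 8)
  ats <- vapply(c(0.5, 1, 2, 4, 6), function(ci) {
    pat <- patient_model(166, 65, cardiac_index = ci)
    cur <- simulate_patient(pat, prot, "ascending_aorta",
                            solver_settings(horizon = 60 + 70 / ci),
                            network = net0)
    arrival_time(cur$ascending_aorta)
  }, numeric(1))
  expect_true(all(diff(ats) < 0))
})
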