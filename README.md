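# ctbolus

Whole-body physiologically based pharmacokinetic (PBPK) simulation of
iodinated contrast-material enhancement for CT angiography.

## What it does, and for whom

Arterial enhancement at contrast-enhanced CT is governed by the patient's
body size and cardiac output and by the injection protocol. Protocol
designers and imaging researchers need to know, *before scanning*, over
which range of cardiac function a protocol keeps the aorta above a
diagnostic threshold (commonly 350 HU). `ctbolus` answers that by
simulating the time–density curve of any organ or vessel in a whole-body
circulation model:

* a directed compartment network (peripheral vein → right heart → lungs →
  left heart → aortic segments → organs → veins), flow-balanced, with the
  stomach, spleen, pancreas and myocardium as distinct organs and a
  portal route into the liver; the reference table (60 kg, left-heart
  output 6500 ml/min) ships as editable TSV;
* tanks-in-series transmission within each compartment (15 sub-units →
  Erlang transit-time dispersion), osmolality/viscosity-scaled diffusion
  of contrast in blood, and linear transcapillary exchange with the
  extracellular space;
* patient scaling by body weight and cardiac output, with
  `CO = 25.3 H^0.725 W^0.425` (ml/min; H cm, W kg) when output is not
  measured, and the DuBois body-surface-area formula for cardiac-index
  conversion;
* curve metrics exactly as used in test-bolus practice: contrast arrival
  time (threshold crossing minus a 2-s lead), peak time, and peak CT
  number, with `enhancement = kappa * concentration` (≈25 HU·ml/mgI at
  120 kVp);
* calibration of the free constants (reference diffusion speed,
  sub-compartment count, HU conversion) against measured — or
  synthetically generated — test-bolus curves, plus cohort validation
  statistics (per-bin 95% CIs, ICC(2,1) agreement);
* cardiac-index sweep experiments (0.1–6.0 l/min/m², step 0.05) for
  coronary (45.5 ml, 8–20 s) and abdominal (74.3 ml, 10–40 s) CTA
  protocol families, with 350-HU adequacy windows per injection duration.

The transport core is a linear mass-balance ODE integrated by a fixed-step
RK4 written in C++ (total iodine conserved to machine precision at every
step); a full sweep of 119 cardiac-index points × 7 durations takes well
under a minute.

## Worked example

```r
library(ctbolus)
pat  <- representative_subject(cardiac_index = 2.5)   # 166 cm, 65 kg
prot <- injection_protocol(study_agent_350(), 45.5, duration = 8)
curves <- simulate_patient(pat, prot, c("ascending_aorta", "abdominal_aorta"),
                           solver_settings(horizon = 120))
do.call(rbind, lapply(curves, enhancement_metrics))
```

prints

```
                            roi cm_at   pt  pctn threshold_delta lead
ascending_aorta ascending_aorta 11.93 22.2 448.7              30    2
abdominal_aorta abdominal_aorta 13.52 24.0 439.9              30    2
```

i.e. for this subject at cardiac index 2.5 l/min/m², contrast arrives in
the ascending aorta 11.9 s after the start of a 45.5-ml injection over
8 s, aortic enhancement peaks 22.2 s after injection start at 449 HU
(well above the 350-HU adequacy threshold), and the abdominal aorta lags
by about 1.5 s. `plot(curves$ascending_aorta)` draws the curve;
`run_sweep(sweep_spec("coronary"))` + `window_table()` tabulate the
cardiac-index windows where PCTN ≥ 350 HU per injection duration.

A command-line interface wraps the same functions:

```sh
exec/ctbolus sweep coronary out/        # grid, windows, figure
exec/ctbolus synth cohort/ 96 1         # synthetic test-bolus cohort
exec/ctbolus calibrate cohort/ cal.json
```

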