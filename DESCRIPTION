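Package: ctbolus
Title: Whole-Body Pharmacokinetic Simulation of Contrast Enhancement for CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates time-density curves of iodinated contrast material in
    organs and vessels with a whole-body physiologically based pharmacokinetic
    (PBPK) compartment model. Each compartment is subdivided into a chain of
    well-mixed sub-compartments (tanks in series) so that intra-organ bolus
    transmission, osmolality- and viscosity-scaled diffusion in blood, and
    transcapillary exchange with the extracellular space are all represented.
    Includes patient scaling by body weight and cardiac output, calibration of
    the free transport constants against measured test-bolus curves, extraction
    of contrast arrival time, peak time and peak CT number, a synthetic
    test-bolus cohort generator, and cardiac-index sweep experiments for
    coronary and abdominal CT angiography protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
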