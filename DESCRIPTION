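Package: nicp
Title: Non-Invasive Intracranial Pressure Estimation from Arterial
    Pressure and Cerebral Blood Flow Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based non-invasive estimation of intracranial pressure
    (ICP) from arterial blood pressure (ABP) and transcranial-Doppler
    cerebral blood flow velocity (CBFv). Implements the simplified
    resistance (SR) estimator, in which the low-pass DC trends of ABP and
    CBFv drive a two-stage resistive reduction of the Ursino intracranial
    circuit, alongside two comparator estimators: a pulsatility-index
    regression and a two-element resistance-compliance model with
    per-beat parameter identification. A lumped-parameter simulator of
    the full Ursino circuit (with a closed-form resistive steady-state
    solver) provides reference CBF and ICP traces for validation, and a
    synthetic waveform generator emulates pulsatile ABP recordings and
    Valsalva-maneuver trials so the entire pipeline is exercisable
    without clinical data. An evaluation harness segments the 45-second
    rest/Valsalva/rest protocol, computes per-phase ICP summaries and
    RMSE against reference ICP, and applies the one-tailed paired t-test
    used to detect maneuver-induced intracranial hypertension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
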