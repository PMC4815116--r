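Package: hifusim
Title: Thermal-Lesion Simulation for High-Intensity Focused Ultrasound with Boiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the thermal lesions produced by high-intensity focused
    ultrasound (HIFU) pulses in layered soft tissue. A linear Rayleigh-integral
    beam stage (or an imported pressure field) provides the steady-state focal
    field of a spherical-cap transducer; an energy-conserving scheme converts
    acoustic intensity into a volumetric heat source; an explicit
    finite-difference solver integrates a generalized Pennes bioheat equation
    with temperature-dependent specific heat (protein denaturation and
    progressive water vaporization) and thermal-dose-dependent perfusion.
    When tissue exceeds the boiling temperature, a phenomenological equivalent
    model redistributes the power intercepted by the bubble cloud into an
    enhanced-heating zone around it. Lesions are extracted from accumulated
    CEM43 thermal dose, and the relation between boiling onset time and lesion
    size is analysed with errors-in-variables (Deming) regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
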