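Package: thermosar
Title: SAR-Based Thermal Dosimetry for Pulsed Electromagnetic Stimulation
    of Implanted Bone Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the thermal safety of pulsed
    electromagnetic-field (PEMF) bone stimulation in the presence of
    metallic orthopedic implants. Computes the magnetic flux density of a
    conical helical coil (on-axis Biot-Savart integrals and a
    segment-summation extension to interior grids), solves the Pennes
    bioheat equation in one dimension with SAR-derived volumetric sources,
    infers the effective specific absorption rate (SAReff) from the initial
    slope of temperature-time curves under a lumped-capacitance balance,
    bounds the internal peak temperature from the measured surface rise,
    and generates synthetic repeated-trial infrared-thermography datasets
    (camera noise, display quantization, shared ambient drift, non-exposed
    reference channel) so that the full pipeline is testable without
    experimental data. Model-vs-measurement agreement metrics (RMSE, MAE,
    MaxAE, Pearson r) and a config-driven pipeline runner are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
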