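Package: bolusplan
Title: Thermal Dosimetry and Water-Bolus Temperature Planning for
    Superficial Hyperthermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based thermal dosimetry for microwave hyperthermia
    treatment planning. Solves the Pennes bioheat equation on labeled
    tissue phantoms with convective (Robin) water-bolus boundary
    conditions, supports constant thermal-stress and temperature-dependent
    (Lang) blood-perfusion models, estimates the water-bolus heat-transfer
    coefficient from transient probe measurements by bounded
    least-squares fitting, tunes total power to a 44 degree Celsius
    healthy-tissue cap, and sweeps water-bolus temperature against
    heat-transfer coefficient to map T50 and mean target SAR as a
    function of target depth. Includes generators for layered and
    cylindrical synthetic phantoms, focal SAR fields and noisy transient
    probe records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
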