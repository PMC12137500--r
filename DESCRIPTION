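Package: thermoloop
Title: Closed-Loop Temperature-Controlled Laser Heating Testbed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual testbed for temperature-feedback control of laser
    photothermal heating. Couples an axisymmetric finite-volume bioheat
    solver (Beer-Lambert volumetric deposition, convective surface, no
    perfusion) with a virtual 32x32 infrared thermopile array and a
    proportional controller that discriminates sample type from the
    temperature rise in the first five seconds of irradiation. Reproduces
    temperature-controlled and equivalent fixed-power irradiation
    protocols, and reports run statistics and Arrhenius thermal-damage
    integrals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
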