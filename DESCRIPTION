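Package: retortsim
Title: Thermal Sterilization Simulation and Retort Schedule Optimization for Canned Puree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric finite-volume simulation of in-can thermal sterilization of
    viscous purees by natural convection, with temperature-dependent thermophysical
    properties, conjugate conduction through a vapor headspace, dynamic F-value
    (lethality) field accumulation, slowest-heating-zone (cold point) localization,
    and retort schedule evaluation and search that trades cold-point lethality
    against the overheated volume fraction responsible for surface browning.
    Includes a pure-conduction mode, a Fourier-Bessel analytic benchmark for a
    finite cylinder, and a synthetic thermal-penetration probe generator with
    sensor lag and measurement noise for model validation workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
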