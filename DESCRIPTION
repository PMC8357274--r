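Package: matprofiler
Title: Biogeochemical Profile Analysis for Laminated Microbial Mats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inverts steady-state microsensor depth profiles (O2, H2S, pH)
    into diffusive fluxes, local volumetric conversion rates, areal and
    depth-averaged rates, sulfide pools and turnover times; processes
    depth-resolved scalar-irradiance spectra into attenuation spectra,
    pigment-band abundance profiles, spectral channel profiles and
    attenuation depths, with a simplified second-derivative hyperspectral
    pigment mapper; computes sulfate reduction rates from 35S radiotracer
    core sections with blank-based detection limits and depth aggregation;
    and scales relative amplicon abundances to absolute cell densities per
    mat layer. A synthetic mat generator (one-dimensional steady-state
    reaction-diffusion solver, synthetic spectral stacks, tracer cores and
    community tables) provides ground truth so every analysis stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
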