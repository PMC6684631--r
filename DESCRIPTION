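Package: subseafloor
Title: Subseafloor Sediment Biogeochemistry: Redox Budgets, Porewater
    Rate Inversion, and Habitable-Volume Mapping
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the biogeochemical footprint of
    subseafloor microbial life. Implements electron-equivalent redox
    bookkeeping for organic carbon, nitrogen and sulfur burial; a total
    alkalinity / DIC seawater carbonate-system solver for the pCO2
    response to alkalinity perturbations; inversion of porewater
    concentration-depth profiles for net respiration rates (Akima-spline
    curvature with tortuosity-corrected diffusivities and Monte Carlo
    uncertainty); a minimum-affinity diffusion-limited model of organic
    oxidation with analytic and finite-difference solutions; conductive
    geotherm / 122 degree C isotherm habitability-volume integration on
    spherical grids; and a sediment-thickness / sedimentation-rate redox
    zonation classifier. A synthetic-data module generates forward-modelled
    porewater profiles and smooth random global grids so the full pipeline
    runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
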