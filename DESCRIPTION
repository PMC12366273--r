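Package: gradientchip
Title: Growth-Factor Gradient Simulation and Vessel/Lipid Morphometry for
    Microfluidic Hydrogel Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing counter-current growth-factor gradients in
    microfluidic hydrogel culture chips and for quantifying the tissues grown
    in them. A finite-difference solver integrates two-dimensional
    diffusion with first-order half-life decay over the culture compartment,
    with media channels acting as decaying fixed-concentration boundaries and
    chip walls as no-flux boundaries, driven by a configurable multi-week
    media-exchange schedule. Concentration fields are summarised into
    EC50-based design metrics: bioactive area fraction, maximum distribution
    distance, time of maximum distribution and limiting-factor identification.
    A morphometry module measures vessel-network topology (junctions,
    endpoints, total length, total area, diameter) and lipid coverage
    profiles from microscopy images, and a synthetic-data module generates
    ground-truthed vessel, lipid and time-lapse images for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
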