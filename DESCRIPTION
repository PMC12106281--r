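Package: hydrosafe
Title: Leaf Hydraulic Vulnerability, Pressure-Volume Traits and Drought
    Safety Margins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring drought-physiology traits of woody plants
    from bench measurements and field campaigns. Quantifies leaf xylem
    embolism from optical image stacks or pre-computed pixel-difference
    event tables, fits sigmoid vulnerability curves (P12/P50/P88),
    extracts turgor loss point, osmotic potential at full turgor and bulk
    elastic modulus from pressure-volume bench-drying series, computes
    hydraulic and stomatal safety margins and predicted percent embolism,
    ranks Gaussian log-link GLMs of canopy damage on trait combinations
    by AIC with Akaike weights and variance-inflation screening, and
    computes the gamma-based Standardized Precipitation Index. Includes a
    seeded synthetic-data generator emulating every input kind with known
    ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    car,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
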