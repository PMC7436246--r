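Package: waxspec
Title: Hyperspectral Prediction and Genetic Mapping of Leaf Epicuticular Waxes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating amounts of leaf epicuticular waxes
    (hentriacontanone-16 and the fatty alcohols octacosanol-1 and
    triacontanol-1) from full-range (350-2500 nm) leaf reflectance spectra,
    and for mapping quantitative trait loci (QTL) for those amounts in an F2
    family. Includes spectral preprocessing (5 nm resampling, replicate
    averaging, Savitzky-Golay first derivatives, quality control), detection
    and unique/shared classification of first-derivative absorption features
    of pure wax standards, partial least-squares regression (NIPALS) with
    PRESS-based latent-vector selection, VIP and standardized-coefficient
    diagnostics, accession-level ANOVA with Tukey letter groupings, and
    Haley-Knott interval mapping with permutation thresholds and 1.5-LOD
    support intervals. A seed-reproducible synthetic-data generator produces
    standard signatures, leaf spectra, accession wax panels, and F2 families
    calibrated to published phenotype and QTL-effect tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    emmeans,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
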