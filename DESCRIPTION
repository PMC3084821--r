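Package: eggmimicry
Title: Tetrahedral Color-Space Analysis of Cuckoo-Host Egg Mimicry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing egg-color mimicry between avian brood
    parasites and their hosts. Maps eggshell reflectance spectra into the
    avian tetrahedral color space (cone quantum catches, Cartesian and
    spherical hue/saturation coordinates, Robinson hue-sphere projections),
    fits a logistic host discrimination function linking color contrast to
    egg-rejection probability with deviance-based backward model selection,
    locates the optimal mimetic egg for a host population and its expected
    rejection rate, estimates Monte-Carlo selection landscapes over
    hypothetical parasite egg colors, and provides distance-based
    permutation statistics (MRPP with chance-corrected effect size, Mantel
    and partial Mantel tests, one-factor permutational MANOVA, a
    multivariate dispersion test, and great-circle distance matrices).
    Includes a synthetic-data generator producing egg reflectance spectra,
    clutch populations with controllable hue bimodality, parasite eggs at
    controlled mimicry offsets, and simulated rejection trials from a known
    discrimination function.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
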