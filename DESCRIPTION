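Package: uvvisbench
Title: Benchmarking Computed Structures and UV-Vis Spectra of Metal Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to benchmark quantum-chemistry predictions of transition
    metal complexes against experiment. Builds continuous UV-vis absorption
    spectra from vertical excitation data (oscillator strengths and
    transition energies) by shifted Gaussian broadening, scores them against
    digitized experimental spectra with a cosine-similarity functional
    maximized over energy shift and broadening width by bounded Nelder-Mead
    search, and scores optimized geometries against crystallographic
    references via optimal rigid-body superposition RMSE and metal-ligand
    bond-length errors (MUE/MSE). Includes per-method aggregation and
    box-plot statistics for ranking methods, and a synthetic-data generator
    with known ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
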