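Package: frostring
Title: Reconstructing Damaging Late Spring Frosts from Tree Rings, Climate
    and Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to reconstruct damaging late spring frost (LSF) events on
    deciduous trees from daily climate data, leaf-out phenology and ring-width
    series. Implements the photoperiod-modulated thermal-forcing (M1) leaf
    emergence model with seeded simulated-annealing calibration and k-fold
    cross-validation; frost safety margins and damage-window flags with
    Theil-Sen/Mann-Kendall trend tests; Tucson/RWL input and output, cubic
    smoothing-spline detrending with a 50 percent frequency cutoff, Tukey
    biweight site chronologies and chronology quality statistics; a
    host-versus-nonhost residual z-score indicator that calls frost years from
    the divergence between a frost-sensitive and a reference species; daywise
    climate-growth correlation grids and superposed epoch analysis of legacy
    effects; plus a synthetic two-site generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
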