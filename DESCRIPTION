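Package: flavassembly
Title: Quantitative Analysis of Flavonoid Supramolecular Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for flavonoid supramolecular-assembly studies:
    four-parameter logistic fitting of enzyme-panel inhibition screens with
    IC50 determination at the 50% crossing and three-way fit categorisation;
    weighted Z-score efficacy ranking of compounds across an enzyme panel;
    mass-weighted radius-of-gyration analysis of molecular trajectories with
    windowed variance-heterogeneity (Levene/Brown-Forsythe) testing;
    geometric detection of pi-stacking contacts and classification of
    assembly graphs into primary (linear) and secondary (branched) fiber
    topologies; and a desk-scale weighted-ensemble engine with a
    variation-maximising (REVO-style) resampler, walker-lineage tracing and
    -ln(p) free-energy profiling over a radius-of-gyration coordinate.
    Synthetic-data generators emulate the statistical structure of the
    screening and simulation inputs so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    car,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
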