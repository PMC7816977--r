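Package: dissolvr
Title: Dissolution Analysis, Formulation Optimization and Oral PBPK
    Simulation for Solid Dispersions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the in-vitro/in-silico evaluation of solid
    dispersions of poorly soluble drugs: model-independent dissolution
    statistics (similarity factor f2, dissolution efficiency, mean
    dissolution time), release-kinetics model selection (zero-order,
    first-order, Higuchi), factorial-design response-surface modeling with
    ANOVA, PRESS and Derringer-Suich desirability optimization, relative
    crystallinity from powder X-ray diffraction patterns, and a mechanistic
    oral-absorption PBPK simulator with gastrointestinal transit
    compartments and virtual populations producing Cmax/Tmax/AUC summaries
    and relative bioavailability. Ships the 18-run diacerein solid
    dispersion design and seeded synthetic-data generators so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
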