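Package: pollinet
Title: Superimposed Plant-Pollinator Network Construction and Structural Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds qualitative bipartite plant-pollinator networks from
    diurnal visitation records and diurnal/nocturnal pollen-load records
    (with a per-specimen five-grain evidence threshold), superimposes them
    with per-link provenance, and analyses their structure: connectance and
    species connectivity, extreme-specialist fractions, Freeman degree
    centralization, NODF nestedness, Barber bipartite modularity optimised
    by simulated annealing with species-role classification, fixed-margin
    (Patefield) null models with z-scores, cumulative connectivity
    distribution fits (exponential, power law, truncated power law),
    frequency-connectivity regressions with slope-heterogeneity tests, and
    interaction rarefaction with bootstrap confidence bands. Includes a
    synthetic community generator with planted module structure for
    method-recovery checks, and a workflow runner producing comparative
    structure reports across the five matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
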