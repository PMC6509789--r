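Package: paretoflux
Title: Multi-Objective Pareto-Front Analysis of Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of stoichiometric metabolic models with an
    emphasis on trade-offs between competing cellular objectives. Implements flux
    balance analysis (FBA), flux variability analysis (FVA), parsimonious
    refinement of alternate optima, single-gene knockout scans, and n-objective
    Pareto-front mapping via the Normalized Normal Constraint method. Also
    provides transcriptome-constrained flux prediction (GX-FBA), Roels
    degree-of-reduction electron accounting, and elemental/charge balance
    checking of reactions and lumped conversion equations. Models are read from
    SBML (Level 2 and Level 3 with the fbc extension) or a plain tabular dialect;
    results are returned as tibbles with broom-style tidiers and ggplot2 plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
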