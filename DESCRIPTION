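Package: oleoflux
Title: Constraint-Based Flux Analysis for Oleaginous Fungal Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for constraint-based analysis of
    compartmentalized genome-scale metabolic models, oriented towards
    polyunsaturated-fatty-acid (PUFA) producing oleaginous fungi. Provides
    flux balance analysis (FBA), flux variability analysis (FVA),
    minimization of metabolic adjustment (MOMA), media-conditioned gene and
    reaction essentiality screens, robustness scans, blocked-metabolite
    (gap) detection, biomass-equation assembly from macromolecular
    composition, and cofactor-centric differential flux accounting. Models
    are read and written as SBML Level 3 (fbc) or as a plain TSV bundle. A
    deterministic synthetic model generator ships a compact oleaginous
    fungus network (glycolysis, pentose phosphate pathway, malic enzyme,
    citrate shuttle, fatty-acid synthesis and the elongase/desaturase chain
    to arachidonic and eicosapentaenoic acid) so the full pipeline can be
    exercised without external data. The linear-programming core is a
    bounded-variable primal simplex implemented in the package; quadratic
    programs use 'quadprog'.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    quadprog,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    boot,
    MASS,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
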