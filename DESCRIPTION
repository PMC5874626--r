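Package: nitroflood
Title: Nitrogen Budgets and T-RFLP Community Analysis for Seawater-Flooded Soils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microcosm studies of agricultural soils flooded with
    seawater. Implements the benthic nitrogen mass balance (core-incubation
    solute fluxes, anoxic jar-regression ammonium production rates with
    porosity correction and depth integration, porewater inventories, and the
    derived potential denitrification and potential ammonium oxidation), a
    T-RFLP fingerprinting pipeline (size-window gating, iterative peak-area
    noise filtration, single-linkage fragment binning into OTUs,
    relative-abundance standardization, singleton/low-abundance filtering and
    log transformation), the community statistics layer (Bray-Curtis
    dissimilarities, UPGMA clustering, NMDS, PERMANOVA with exhaustive or
    Monte-Carlo permutation, environmental vector fitting, OTU sharing counts
    and abundance-module detection), qPCR absolute quantification against
    dilution-series standard curves, and a seeded synthetic-data generator
    with known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
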