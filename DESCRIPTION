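Package: mclselect
Title: Chemical-Space Sampling of Measurable Compound Lists for Non-Target LC-HRMS
Version: 0.1.0
Authors@R: person("MCL", "Maintainers", email = "mcl@example.org", role = c("aut", "cre"))
Description: Builds measurable compound lists (MCLs) for non-target
    LC-HRMS method development from large compound tables. A 13-variable
    physicochemical/structural model (molecular weight, XLogP, TPSA,
    H-bond donor/acceptor counts, six elemental mass defects, predicted
    environmental mobility class, and predicted electrospray ionization
    efficiency) is standardized and decomposed by PCA; the score space is
    sampled by symmetric gridding; candidates are filtered for structural
    dissimilarity and ionization compatibility and ranked into ESI(+) and
    ESI(-) candidate lists with coverage diagnostics. Includes a seeded
    synthetic-data generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
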