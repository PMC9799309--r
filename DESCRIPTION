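Package: metox
Title: Methionine Oxidation Liability from Solvent Environment Descriptors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of methionine oxidation liability in antibody
    variable regions from static structures and conformational ensembles.
    Computes per-methionine solvent-environment descriptors (static and
    dynamic side-chain solvent-accessible surface area by the
    Shrake-Rupley method, the two-shell water coordination number WCN,
    and the hydroxyl coordination count of nearby Ser/Thr/Tyr side
    chains), classifies residues as oxidation-prone by threshold rules
    including the combined WCN-OH rule, and evaluates predictions
    against observed oxidation data with confusion matrices, bootstrap
    errors on sensitivity and specificity, and semiquantitative
    correlation metrics. Includes a synthetic solvated-probe generator
    for validation and packaged reference benchmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
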