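Package: picdtox
Title: PBPK-Based Contextualization of In Vitro Hepatotoxicity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal whole-body physiologically-based pharmacokinetic (PBPK)
    simulator coupled to an in vitro to in vivo contextualization workflow for
    drug-induced hepatotoxicity. In vitro hepatocyte exposures are mapped to
    equivalent in vivo doses by matching the simulated area under the
    liver-interstitial concentration-time curve to the assay exposure;
    transcriptomic responses are then transferred to therapeutic and toxic
    doses to compute per-gene and per-process toxic changes. Downstream
    analytics cover over-representation of toxicity gene sets, Ward clustering
    of drug response profiles, common and individual molecular biomarker
    identification, drug-drug interaction prediction from shared biomarkers,
    and differential response pathway construction. A seeded synthetic-data
    generator emulating hepatocyte response tensors makes the full pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
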