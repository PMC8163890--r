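Package: consortia
Title: Rational Design and In Silico Validation of Live Biotherapeutic
    Bacterial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bottom-up rational design of live biotherapeutic
    products (LBPs): profiling candidate gut strains for therapeutic functions
    (short-chain fatty acid, GABA and indole synthesis, siderophore synthesis
    and uptake, bile-salt deconjugation and secondary bile acid conversion,
    antimicrobials) from genome annotation tables; screening exclusion
    criteria (transferable antibiotic resistance, virulence factors);
    fragment-based average nucleotide identity for species delimitation;
    constraint-based metabolic modelling with flux balance analysis,
    exact minimum-penalty gapfilling and single-omission auxotrophy
    detection; compartmentalised community models with max-min community
    FBA, strain-interaction and dropout analysis; a redundancy- and
    complementarity-constrained consortium selector with an exhaustive
    oracle; comparative-Ct qPCR quantification; and a synthetic-universe
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
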