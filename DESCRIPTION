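Package: allofold
Title: Thermodynamic Linkage Analysis of Fold-Switch-Driven Protein Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the thermodynamic analysis of allosteric protein
    assembly driven by a monomer fold switch. Implements closed-form
    two-state folding models (linear extrapolation, Gibbs-Helmholtz
    stability curves, chevron kinetics), a five-species mass-action
    linkage model coupling a native-to-switched conformational
    transition to hexamer and dodecamer formation under temperature,
    protein-concentration and peptide-effector control, forward
    synthesis of the observables used to probe it (fluorescence and CD
    melts, DSC excess heat capacity, species distributions, peptide
    titrations), competitive-inhibition Michaelis-Menten analysis,
    seeded synthetic-data generators, weighted nonlinear least-squares
    fitting with parameter-recovery studies, and sequence-mass and
    D6-toroid geometry utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
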