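Package: fastz
Title: Fast-Z Molecular Evolution and Mating-System Comparisons on Synthetic Shorebird-Style Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for fast-Z evolution in birds with
    diverse mating systems. Generates synthetic inputs (phylogenies, codon
    alignments evolved under a Goldman-Yang-style codon model with
    partition- and mating-system-dependent dN/dS, sexed read-depth tables,
    discrete mating-system traits, and sex-linked effective-size demography),
    assigns scaffolds to the Z chromosome from female:male coverage ratios,
    estimates synonymous and non-synonymous substitution rates per gene
    (Nei-Gojobori counting, pairwise codon maximum likelihood, and ancestral
    reconstruction with per-branch counting), applies the filtering,
    concatenation and bootstrap rules of comparative fast-Z analyses, and
    performs the downstream statistics: paired and Welch t-tests,
    phylogenetic generalized least squares with maximum-likelihood Pagel's
    lambda, and two-state Mk ancestral-state reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
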