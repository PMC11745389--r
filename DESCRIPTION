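Package: epiland
Title: Epistasis Inference, Ruggedness Statistics, and Evolutionary
    Dynamics on Complete Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Steven", "Albright", email = "salbright@example.org",
           role = c("aut", "cre"))
Description: Tools for combinatorially complete biallelic fitness
    landscapes (all 2^L genotypes over L mutated sites), motivated by
    deep mutational scans of antibody variable regions.  Implements
    specific-epistasis (Ising-type, up to third order) and global-epistasis
    (monotone nonlinearity of an additive latent phenotype) model
    inference with cross-validation, Walsh-Hadamard spectral analysis and
    band-pass denoising, directed and generalized gamma ruggedness
    statistics, slope-to-roughness funneling metrics, NK model landscape
    generation with topography-constrained ensembles, strong-selection
    weak-mutation absorbing Markov chains, Wright-Fisher dynamics on a
    ring lattice with tunable migration range, mutational-path ensembles
    with scaled path entropy and mutation-ordering statistics, and seeded
    2D embeddings of genotype space.  Includes a synthetic generator for
    hotspot-structured landscapes and noisy replicate measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
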