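Package: admixped
Title: Admixture Proportions of Parents, Grandparents and
    Great-Grandparents from a Single Phased Genome
Version: 0.1.0
Authors@R:
    person("admixped", "developers", email = "admixped@example.org",
           role = c("aut", "cre"))
Description: Infers the admixture proportions of the recent ancestors
    (parents, grandparents, great-grandparents) of a single admixed
    individual from its phased diploid genome, using a hidden Markov
    model over ancestral configurations of a K-generation pedigree.
    The hidden state at each SNP jointly encodes a phase-switch bit,
    the population-of-origin of each generation-K founder, and the
    recombination arrows of the pedigree; a divide-and-conquer
    matrix-vector product makes the forward algorithm run in
    O(N log N) per site instead of O(N^2). Per-founder ancestry switch
    rates are estimated by maximum likelihood (L-BFGS on
    logit-transformed rates with finite-difference gradients) and
    converted to stationary admixture proportions. Includes SNP
    pruning and phase-switch-error cleanup, a Wright-Fisher admixture
    simulator with tract tracking for ground truth, best-match error
    evaluation, and a command-line interface over phased VCF, allele
    frequency and genetic map files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
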