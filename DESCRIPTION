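Package: argrl
Title: Maximum-Parsimony Ancestral Recombination Graphs by Reinforcement
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs maximum-parsimony ancestral recombination graphs
    (ARGs) for polarized SNP haplotype samples by treating genealogy
    building as a shortest-path Markov decision process over coalescence,
    mutation and recombination events.  Provides an exact tabular layer
    (value iteration, exhaustive enumeration and counting of minimal ARGs
    together with their policy-induced probabilities), a gradient
    Monte-Carlo reinforcement-learning agent with a block-of-markers
    feature representation and a small feed-forward value network,
    ensemble policies (mean value, majority vote, minimum length) for
    generalizing to samples unseen during training, a re-implementation
    of the ARG4WG heuristic as a baseline, and a seeded
    coalescent-with-recombination simulator for generating test data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
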