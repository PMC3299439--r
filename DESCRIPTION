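Package: gapml
Title: Jukes-Cantor Maximum Likelihood on Gapped Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how maximum-likelihood phylogeny estimation
    under the Jukes-Cantor substitution model behaves when alignment gaps
    are treated as missing data. Implements pruning-based likelihood
    computation with missing-data marginalization, exhaustive
    maximum-likelihood search over unrooted binary topologies, a seeded
    simulator of sequence evolution with substitutions and single-residue
    indels down a tree, binary gap coding of gapped alignment columns, and
    a Fitch-parsimony contrast estimator on the coded gap characters.
    Includes experiment drivers demonstrating that monotypic gapped
    alignments make every topology an equally good maximum-likelihood
    solution, while the gap pattern in the same alignments still separates
    topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
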