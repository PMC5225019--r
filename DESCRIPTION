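Package: hiMSA
Title: Hierarchical Multiple Sequence Alignment by Bayesian Partitioning
    and Minimum Description Length Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneously aligns a protein superfamily, partitions it
    into hierarchically nested subgroups defined by discriminating
    residue patterns, and selects model complexity by the minimum
    description length principle. Implements Gibbs sampling over a
    profile hidden Markov model posterior with Dirichlet mixture
    emission priors and integrated position-specific gap penalties,
    Bayesian partitioning with pattern selection (BPPS) over rooted
    node hierarchies with a reject node for unrelated sequences,
    simulated annealing over tree moves, hierarchical (lineage-specific)
    sub-alignments and hidden Markov models, BILD and Delta-BILD column
    information scores, contrast-alignment text rendering, and a
    synthetic sequence generator with planted hierarchies for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
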