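Package: haplodem
Title: Haplotype-Based Phylogeography and Historical Demography for
    Mitochondrial Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-level analysis of aligned mitochondrial
    DNA sequences sampled from multiple demes: haplotype collapsing and
    per-deme molecular diversity (haplotype diversity, mean pairwise
    differences, nucleotide diversity), pairwise PhiST and one- and
    two-level analysis of molecular variance (AMOVA) with permutation
    tests, statistical-parsimony haplotype networks with a 95 percent
    connection limit, multivariate spatial autocorrelograms and Mantel
    tests for isolation by distance, mismatch-distribution fitting of
    sudden demographic and spatial (infinite-island) expansion models with
    parametric-bootstrap goodness of fit and conversion of mutation-scaled
    parameters to years and effective sizes, Fu's FS neutrality test, and
    a two-deme isolation-with-migration coalescent sampler under a
    finite-sites HKY model. A built-in structured-coalescent simulator
    generates study-like synthetic data sets so every analysis is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
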