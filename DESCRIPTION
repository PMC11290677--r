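Package: divopt
Title: Cost-Optimal Sampling Protocols for Taxonomic, Phylogenetic and
    Functional Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of cost-optimal biodiversity survey protocols across the
    three classical diversity dimensions. Given multi-method survey data
    (samples by species abundance matrices tagged with method and site),
    rooted trees with branch lengths, trait tables and a fixed plus variable
    cost model per method, the package searches for the allocation of
    sampling effort per method that maximizes expected sampled alpha-diversity
    (inventorying) or minimizes bias in beta-diversity (monitoring).
    Taxonomic, phylogenetic and functional diversity are all measured as
    branch-length sums on, respectively, a unit star tree, a phylogeny and a
    Gower-distance neighbor-joining functional tree, and beta-diversity is
    partitioned into replacement and richness-difference components.
    Exhaustive and greedy nested optimizers with Monte-Carlo subsampling or
    exact subset enumeration are provided, together with a survey simulator
    with method-specific detection biases for protocol benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    cluster,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
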