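Package: gcntools
Title: Gene Coexpression Networks, Node Hierarchy and Community Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene coexpression networks from genes-by-samples
    expression matrices using Pearson correlation with an automatically
    selected link-strength threshold, validates their scale-free status with
    a discrete power-law fit and Kolmogorov-Smirnov bootstrap, categorizes
    nodes into hubs, VIPs and high-hubs from concentric node degrees,
    detects communities by multilevel modularity optimization, and contracts
    networks into their coarse-grained community structure. Includes a
    synthetic-data module that generates modular expression matrices and
    benchmark graphs with known ground truth, a two-group differential
    expression screen, and an end-to-end pipeline that compares networks
    built from differentially expressed and whole-transcriptome gene sets
    across two sample groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
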