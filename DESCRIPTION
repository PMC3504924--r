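Package: covernet
Title: Cover-Based Discovery of Multi-Class Discriminative Subnetworks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers protein subnetworks whose aggregate expression
    discriminates multiple phenotype classes. Implements a greedy
    set-cover search (COBALT) for one-vs-all discriminative subnetworks
    on a protein-protein interaction network, additive greedy searches
    maximizing mutual information for one-vs-all and all-vs-all
    objectives, size-stratified permutation tests for subnetwork
    significance, and subnetwork-activity classification of sample
    stage with a Gaussian naive Bayes classifier. Includes a synthetic
    data generator with planted dysregulated modules and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
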