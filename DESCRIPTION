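Package: protodom
Title: Agent-Based Simulation of Canine Proto-Domestication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based simulation of single-trait evolution of human
    tolerance in a prehistoric canine population.  Canines compete for food in
    two niches (scavenged human food and wild food) under a bounded
    random-walk resource environment, reproduce by a logistic-derived female
    breeding probability with optional assortative mate preference, and are
    subject to age-dependent non-starvation mortality.  Divergence into
    wolf-like and dog-like sub-populations is detected with Hartigan's dip
    test of unimodality applied to decennial censuses and a streak-based
    speciation rule.  Includes a replication harness with persistence retries
    and global sensitivity analyses (eFAST and PRCC) with a dummy parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, yaml, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), boot, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
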