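Package: msatphylo
Title: Microsatellite Content and Its Tempo and Mode of Evolution Across
    Phylogenies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects perfect 2-6 bp-motif tandem repeats (microsatellites)
    in genome assemblies and analyses how microsatellite content evolves
    across a time-calibrated phylogeny. Provides exact per-period repeat
    scanning with per-period minimum copy-number thresholds, Brownian-motion
    rate estimation by restricted maximum likelihood with ancestral-state
    reconstruction and per-lineage tip rates, a two-state Markov model of
    centromere type with stochastic character mapping, a censored two-rate
    Brownian test over stochastic maps, simulation-null phylogenetic ANOVA,
    and phylogenetic linear models with parametric bootstrap. Includes
    generators for birth-death trees, Brownian and Markov trait histories,
    and genomes with planted repeats of known coordinates, so the whole
    pipeline can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phytools,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
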