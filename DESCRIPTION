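Package: corepan
Title: Pan-Genome, Genome Identity and Host-Adaptation Analysis for
    Bacterial Genome Sets
Version: 0.1.0
Authors@R:
    person("Core", "Pan", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of bacterial genome collections at the
    gene-family level. Builds gene families from translated coding
    sequences under an identity/coverage homology rule with optional
    six-frame rescue of unannotated loci, computes pan- and core-genome
    accumulation curves with power-law fits, fragment-based average
    nucleotide identity (ANI) and filtered best-hit average amino acid
    identity (AAI), host-grouped core-gene partitions with functional
    category tabulation, and root-to-tip node-depth statistics on rooted
    phylogenies with an exact Wilcoxon rank-sum comparison. Includes a
    genome-evolution simulator (gene gain/loss on a birth tree plus
    per-site substitution) that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
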