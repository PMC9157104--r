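Package: poolscan
Title: Differentiation Mapping from Pooled Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("poolscan", "developers", email = "poolscan@example.org",
           role = c("aut", "cre"))
Description: Genome-wide differentiation mapping between pooled sequencing
    libraries using the absolute allele frequency difference (AFD). Reads
    per-pool nucleotide counts from samtools-mpileup text or popoolation2
    sync tables, calls and filters biallelic SNPs, smooths AFD over sliding
    windows, extracts candidate regions around top-differentiation SNPs,
    intersects them with a GFF3 gene annotation, builds cross-population
    allele panels, and evaluates validation-panel genotype counts with a
    Monte-Carlo Hardy-Weinberg deviance test. A forward simulator of a
    two-locus plate-morph architecture (a major biallelic locus plus a
    conditional modifier locus) generates pooled read counts with truth
    tables so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    optparse,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
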