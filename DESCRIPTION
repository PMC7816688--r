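Package: gvpop
Title: Consensus-Free SNP Analysis of Granulovirus Isolate Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative, consensus-free analysis of the population structure
    of baculovirus isolates from multi-isolate per-site nucleotide count data.
    Implements stringency filtering of SNP sites, assignment of SNP
    specificity to exact isolate sets, genotype-mixture quantification from
    marker-set allele frequencies, classification of SNPs against an ORF
    annotation on a circular genome, flank-anchored counting of a 12-bp
    tandem repeat directly from reads, and hierarchical clustering on
    principal components (HCPC) of the SNP frequency matrix. A synthetic-data
    generator produces references, genotype panels, mixed-isolate count
    matrices and repeat-region reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
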