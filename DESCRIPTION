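Package: paratype
Title: Copy Number and Allele-Level Genotyping of Highly Homologous Gene
    Families from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotyping pipeline for copy-variable, highly homologous gene
    families such as the killer-cell immunoglobulin-like receptor (KIR)
    complex. Preprocesses an allele database by imputing uncharacterized
    positions from per-gene multiple sequence alignments, extending
    untranslated regions with donor sequence, and selecting a minimized,
    diversity-maximizing reference allele set. Determines per-gene copy
    number across a batch of samples from read counts that align uniquely
    to each gene, normalized against a framework gene, and calls
    allele-level genotypes through an iterative genotype-matched alignment
    workflow with SNP mismatch scoring, virtual sequence probes, and
    reference refinement. Includes a truth-labeled paired-end read
    simulator for gene-content-variable haplotypes, a shared k-mer
    homology analysis, and tracing of misaligned reads to their source
    gene.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    stringi,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
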