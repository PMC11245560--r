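Package: hybridtriad
Title: Detecting Diploid Fungal Hybrids and Dissecting Transgressive Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An inference chain for recognising intraspecific diploid fungal
    hybrids and characterising heterosis at the transcriptome level. Provides
    ploidy diagnostics from canonical k-mer spectra and heterozygous-site
    allele-frequency profiles, SNP filtering with windowed heterozygosity and
    neighbor-joining phylogenies on IUPAC-encoded genotype matrices,
    parental-origin inference from diagnostic heterozygous SNPs, subgenome
    assignment by k-mer containment, windowed pairwise identity between
    haplotypes, TMM/CPM/FPKM normalisation, homoeolog expression bias,
    additive/nonadditive triad classification (expression-level dominance,
    transgressive up/down regulation), allele-specific expression read rules
    with cis/trans partitioning, and hypergeometric term enrichment. A
    synthetic-data module generates every input with known ground truth so
    the whole pipeline is exercisable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    withr,
    data.table,
    jsonlite,
    ape,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer
Config/testthat/edition: 3
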