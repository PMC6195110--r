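Package: radmendel
Title: Pedigree-Based Consistency Assessment of Whole-Genome-Amplified
    RADseq Haplotypes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the accuracy of RADseq libraries built from
    whole-genome-amplified (WGA) DNA of haplodiploid insects using a
    pedigree design: a haploid F0 male and diploid F0 female, one
    genotyped virgin F1 female, and a pool of haploid F2 males used as a
    WGA-free control.  Reads and filters locus-by-sample haplotype
    matrices, simulates crosses with WGA-style noise (allele dropout,
    spurious alleles, missingness), classifies loci against
    arrhenotokous-Mendelian expectations, attributes incompatible loci
    to a culprit sample, counts restriction cut sites in genome
    assemblies, and reproduces the study-level summary arithmetic.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
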