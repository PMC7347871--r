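Package: mitodui
Title: Mitogenome Divergence, Compositional Skew and Heteroplasmy
    Quantification for Doubly Uniparental Inheritance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for doubly uniparental inheritance (DUI) of
    mitochondrial DNA in bivalves. Reads annotated circular mitogenomes
    (GenBank flat file or FASTA), computes sliding-window AT/GC skew and GC
    content with neutral-site filtering, per-gene and overall p-distances
    between F-type and M-type mitogenomes with bootstrap standard errors,
    population-genetic summaries of haplotype sets (segregating sites,
    haplotype diversity, Watterson's theta, nucleotide diversity, Tajima's D,
    Nei-Gojobori Ka/Ks with Jukes-Cantor correction), qPCR standard-curve
    calibration and absolute mtDNA copy-number quantification with
    confidence intervals, NGS read-count heteroplasmy ratios, and the
    mixture-regression extrapolation of M-mtDNA copies per sperm cell.
    Includes seeded synthetic-data generators (mitogenome pairs, neutral
    coalescent haplotypes, codon alignments with chosen omega, qPCR tables)
    so every stage is testable against known truth without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
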