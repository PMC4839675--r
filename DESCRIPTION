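Package: methorigin
Title: Parent-of-Origin Methylation Analysis for Trisomy 21
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytical chain for determining parent-of-origin effects of
    trisomy 21 on DNA methylation at candidate imprinted loci. Quantifies
    methylation from methylation-sensitive restriction enzyme PCR
    (MSRE-PCR) peak areas with an amplification-imbalance correction
    factor, infers the parental origin of a supernumerary chromosome 21
    from STR trio genotypes by allele segregation and dosage, calls
    allele-specific methylation from dual-enzyme (HhaI/McrBC) SNuPE
    genotypes, screens SNPs for monoallelic versus biallelic expression
    from read sets via degenerate substring queries with a chi-square
    test against 50/50, and scans DNA sequences for tandem arrays of a
    degenerate IUPAC motif. A synthetic-data module generates trio
    genotypes, peak-area quartets, allele-specific read sets and
    motif-bearing sequences with known truth so every stage is testable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
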