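Package: lionpanel
Title: Diagnostic SNP Panel Design and Population Assignment from Low-Coverage Lion Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genotyping workflow used in range-wide lion
    (Panthera leo) conservation genetics: masking and filtering of SNP calls
    from low-coverage whole genomes, design of a small diagnostic panel of
    autosomal and mitochondrial SNPs (including numt screening of
    mitochondrial assay candidates), panel-based sample quality control,
    mitochondrial haplogroup assignment with confidence grading, supervised
    clade assignment under Hardy-Weinberg genotype likelihoods, observed
    heterozygosity at the individual and population level, and the
    ABBA-BABA D-statistic with bootstrap significance. A hierarchical
    Balding-Nichols simulator generates structured synthetic cohorts
    (two subspecies, four clades, admixture, Poisson coverage with allelic
    dropout, mitochondrial haplogroups and numt decoys) so the whole
    pipeline can be exercised and validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
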