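Package: truneo
Title: Multi-Factor Neoantigen Prioritization from Somatic Variants
Version: 0.1.0
Authors@R:
    person("TruNeo", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies and ranks candidate tumor neoantigens from annotated
    somatic variants, HLA class-I genotype calls and tumor expression data.
    Implements high-confidence somatic SNV/InDel filtering with per-read
    quality rank-sum tests, consensus HLA genotyping across two callers and
    two samples, an HLA loss-of-heterozygosity test on paired allele
    coverage, 8-11-mer mutant peptide enumeration from missense, frameshift,
    in-frame indel and fusion events, a composite pMHC immunogenicity score
    combining binding affinity, proteasomal cleavage, TAP transport,
    expression, clonality and a six-class epitope taxonomy, plus benchmarking
    metrics (recall at k, true-positive rate), a TCR clonotype-expansion
    test and a synthetic patient-bundle generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
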