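Package: mirtarsnp
Title: SNP-Driven Gain and Loss of Plant miRNA-Target Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates plant microRNA hairpin loci from collapsed small-RNA
    reads, scores miRNA-target complementarity with a position-weighted
    penalty scheme, computes nucleotide diversity (pi) across miRNA-related
    locus classes with a length-matched permutation test, reconstructs
    group-specific snp-miRNA and snp-mRNA sequences from population variants
    to call genotype-group-unique miRNA targets, and validates predicted
    cleavage sites against degradome (PARE) 5'-tag profiles with
    CleaveLand-style category classification. Ships a seeded synthetic-data
    generator that plants hairpins, binding sites, group-differentiated SNPs
    and degradome peaks with machine-readable ground truth, so the whole
    pipeline can be exercised end-to-end with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
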