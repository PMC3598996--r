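Package: keyimpute
Title: Genotype Imputation Evaluation with Key-Animal Reference Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and evaluate genotype-imputation studies in
    pedigreed livestock populations. Simulates half-sib pedigrees with
    linkage-disequilibrium-structured SNP genotypes, applies a quality-control
    cascade (call rate, minor allele frequency, Hardy-Weinberg, Mendelian
    consistency, pedigree-versus-genomic relationship screening), selects
    reference ("key") animals that maximise the captured gene pool via the
    numerator relationship matrix, masks validation genotypes down to a
    low-density panel, imputes them with a built-in Li-Stephens haplotype
    hidden Markov model or an external tool adapter, and reports imputation
    accuracy (allelic and genotypic concordance, true-imputed genotype
    correlation, allele-frequency-stratified LOESS curves, accuracy by number
    of close relatives). Includes a segment-based detector of misplaced SNP
    driven by local imputation error, with linkage-disequilibrium
    localisation of the likely true position.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
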