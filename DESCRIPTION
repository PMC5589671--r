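Package: strforensics
Title: Forensic Population Genetics for Combined Autosomal and Y-STR Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the forensic population-genetic characterisation of
    short tandem repeat (STR) panels that co-amplify autosomal and
    Y-chromosomal loci.  Provides genotype-table input/output with
    microvariant allele support, forensic efficiency parameters (matching
    probability, power of discrimination and exclusion, polymorphism
    information content, typical paternity index, observed and unbiased
    expected heterozygosity, combined powers in arbitrary-precision
    decimals), Monte-Carlo exact tests of Hardy-Weinberg equilibrium and
    pairwise linkage disequilibrium, Y-STR haplotype diversity statistics
    (Nei gene diversity, haplotype diversity, discriminatory capacity),
    Weir-Cockerham Fst and AMOVA-style Rst population differentiation with
    permutation p-values, classical genetic distances with neighbor-joining
    trees, principal component and classical multidimensional scaling
    ordination, and seeded synthetic-population generators (Hardy-Weinberg
    and Balding-Nichols models) for validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
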