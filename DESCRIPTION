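Package: kaspanel
Title: KASP SNP Panel Design and Association Genetics for Inbred Crop
    Diversity Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing biallelic KASP genotyping panels from
    transcriptome consensus sequences of two inbred accessions, and for
    analysing the resulting genotype data in a crop diversity set:
    marker diagnostics (polymorphism information content, Hardy-Weinberg
    exact test, linkage disequilibrium r2 and its decay with physical
    distance), admixture-based population structure with Evanno delta-K
    model choice, REML analysis of alpha-design insect-count trials
    (variance components, predicted means, maximum LSD, heritability),
    and dual marker-trait association combining a Kruskal-Wallis rank
    scan with an EMMA-style kinship mixed model under Q+K genomic
    control.  A synthetic-data module generates every input with known
    ground truth so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    lme4,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
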