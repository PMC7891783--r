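Package: pgximpact
Title: Actionable Pharmacogenetic Variant Cataloging and Population
    Prescription-Impact Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Secondary pharmacogenetic analysis of exome cohorts: loading and
    validating catalogs of actionable pharmacogenetic variants and
    high-confidence pharmacogenes, star-allele diplotype calling from unphased
    genotypes, declarative diplotype-to-phenotype translation in the CPIC
    style, Hardy-Weinberg projection of phenotype and carrier frequencies
    (autosomal and X-linked), rare predicted-deleterious variant
    classification with CADD/REVEL/LOFTEE-style threshold rules, per-sample
    variant burden summaries, and projection of population-level prescription
    impact (patient headcounts and drug expenditure) from phenotype
    frequencies. Includes a seeded synthetic-cohort generator emulating
    Hardy-Weinberg genotypes, HLA typing tables, variant annotation tables,
    and prescription extracts, so the full pipeline can be exercised without
    access to protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
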