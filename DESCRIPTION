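Package: hbfedit
Title: Genotype-Phenotype Analysis of Fetal Hemoglobin Regulation in
    CRISPR-Edited Erythroid Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-colony functional analysis of fetal
    hemoglobin (HbF) regulation. Calls per-allele CRISPR editing outcomes
    in erythroid burst-forming-unit (BFU-E) colonies and encodes them as
    allelic-series dosages (HBG1/2 promoter 13 bp element, BCL11A exon
    2/4, ZBTB7A, and beta-globin locus deletions); converts qPCR Ct
    values into globin expression relative to the HBA1/2 endogenous
    control and beta-like globin fractions; fits dosage-by-dosage
    interaction linear mixed models by REML with Satterthwaite
    approximate degrees of freedom, via a formula interface returning a
    classed fit with the usual methods; normalizes locus-specific
    chromatin interaction profiles (per-kilobase relative interaction
    frequency with significance filtering, and 3C ligation qPCR against
    a TUBA1A control); and simulates complete synthetic colony studies
    with donor and guide random effects so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmerTest,
    Biostrings
Config/testthat/edition: 3
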