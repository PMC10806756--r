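Package: smrtriage
Title: Summary-Data Mendelian Randomization for Drug-Target Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nominates and triages therapeutic gene targets from GWAS and
    molecular QTL summary statistics. Implements single-SNP summary-data-based
    Mendelian randomization (SMR), the HEIDI heterogeneity test separating
    pleiotropy from linkage, and a multi-SNP SMR test, with linkage
    disequilibrium estimated from a reference genotype panel. Downstream
    stages apply annotation/region/multiple-testing filters, summarize
    multi-disease overlap and direction of effect, classify genes into
    novel/known/difficult druggability tiers, expand curated companion-gene
    networks with proxy-drug and liver-toxicity annotation, and score
    single-nucleus expression support via expression percentile ranks (EPR).
    A synthetic-data module generates LD panels, summary statistics under
    pleiotropy/linkage/null scenarios, snapshot annotation tables, and counts
    matrices for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
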