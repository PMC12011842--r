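Package: faerslahl
Title: Disproportionality Analysis of Drug-Induced Lactic Acidosis in FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for pharmacovigilance signal detection of
    medication-induced lactic acidosis and hyperlactatemia (LAHL) in
    spontaneous adverse-event reports distributed in the FDA Adverse Event
    Reporting System (FAERS) quarterly ASCII dialect. Reads and writes the
    dollar-delimited DEMO/DRUG/REAC/THER/OUTC tables and DELETED case lists,
    deduplicates reports by the CASEID/FDA_DT/PRIMARYID rule, standardizes
    drug names to ingredient-combination keys, defines event cases by a
    MedDRA preferred-term set, builds per-drug case/non-case 2x2 contingency
    tables, and computes reporting odds ratios (ROR) with 95% confidence
    intervals, proportional reporting ratios (PRR) and Pearson chi-square
    statistics with the standard signal criteria. Includes a synthetic
    FAERS-like report generator with planted odds ratios for end-to-end
    validation, descriptive summaries of demographics, outcomes and onset
    times, and a reconstruction oracle that inverts printed summary
    statistics back to full contingency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
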