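Package: targetrank
Title: Evidence-Weighted Therapeutic Target Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico drug-target triage pipeline for inflammatory disease
    programs. Aggregates per-target evidence from literature asset classes
    (publications, clinical trials, patents, grants, congresses, news, theses),
    structured genomic databases, differential-expression tables and annotated
    variant calls; scores each asset class by recency, impact factor, trial
    phase/status and mention position with cohort-wide min-max scaling; applies
    a relevance cascade (minimum document count with a single-class pathway
    rescue); hard-filters variants on GATK-style quality metrics and calls
    loss-of-function on VEP-style annotations; classifies targets for
    druggability, safety, biomarker potential, tissue expression and novelty;
    and combines everything into a weighted 40/60 literature/disease priority
    score with deterministic ranking. Includes a synthetic-cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    vcfR,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
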