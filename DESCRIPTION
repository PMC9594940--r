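Package: irhpc
Title: Immune-Related Histologic Phenotype Scoring and Neoadjuvant Pathologic Response Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating response to neoadjuvant anti-PD-1
    immunotherapy in resected non-small cell lung cancer and for predicting
    that response from pretreatment biopsies. Implements the immune-related
    histologic phenotype criteria (irHPC), an additive pretreatment score
    over four biopsy features (tumour-infiltrating lymphocytes, eosinophils
    and dense plasma cells scored positively, neutrophils negatively) with a
    2-point predicted-responder cutoff; per cent residual viable tumour
    (%RVT) with and without necrosis in the denominator and the
    cPR/MPR/pPR/nPR response classes; the derived neutrophil-to-lymphocyte
    ratio (dNLR) and PD-L1 tumour proportion score rules; inter-rater
    agreement statistics (overall per cent agreement with confidence
    interval, Fleiss' kappa with standard interpretation bands);
    Kaplan-Meier disease-free and overall survival summaries; a synthetic
    cohort generator for end-to-end testing; and a pipeline that assembles
    a structured study report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
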