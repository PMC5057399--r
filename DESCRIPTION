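Package: adlcat
Title: Computerized Adaptive Testing Engine for Activities of Daily Living Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Item-response-theory engine for computerized adaptive testing (CAT)
    of activities-of-daily-living (ADL) instruments. Ships the dichotomous Rasch
    23-item comprehensive ADL (Barthel Index + Frenchay Activities Index) bank
    and the 34-item generalized partial credit model (GPCM) ADL banks with
    sex-specific parameters; simulates response matrices from a standard-normal
    person population; estimates person measures by maximum likelihood (MLE),
    posterior mode (MAP) and posterior mean (EAP); administers adaptive tests
    with maximal-information item selection and compound reliability/convergence
    stop rules; compares CAT against full-length (non-adaptive) scoring by
    correlation, paired difference ratios and efficiency; and derives
    norm-referenced person-strata cutpoints on the T-score scale via a
    reliability-based strata count, one-dimensional k-means and a maximal
    sensitivity-plus-specificity search between adjacent normal clusters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
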