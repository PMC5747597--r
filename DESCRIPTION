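Package: eshval
Title: Blood Pressure Device Validation Statistics Under the ESH International Protocol
Version: 0.1.0
Authors@R:
    person("eshval", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A complete statistical pipeline for test-retest validation studies
    of automatic blood pressure monitors under the European Society of
    Hypertension International Protocol (2010 revision), including the
    heart-rate extension used when a cuff device also reports pulse. Implements
    difference selection and inclusive banding for the alternating seven-reading
    sequence, requirement scaling to arbitrary multiples of the 33-subject base
    design, the two-phase (pair-level and subject-level) pass/fail evaluation,
    test-retest reliability (two-way ANOVA intraclass correlation with
    F-distribution confidence intervals, standard error of measurement, paired
    t-tests, Monte-Carlo Lilliefors normality checks), between-device agreement
    (mean comparisons, Pearson correlation, Bland-Altman limits of agreement),
    paired-design sample-size computation with attrition inflation, and a
    calibrated synthetic-study generator so the whole pipeline runs and is
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
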