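Package: rrforced
Title: Forced-Response Randomized Response Surveys of Sensitive Behaviours
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing surveys of sensitive behaviours collected
    with the forced-response randomized response design. Represents card-deck
    randomization devices and their induced misclassification line, computes
    design-corrected prevalence estimates with variances and truncated Wald
    confidence intervals (globally and by subgroup), tests direct-versus-
    indirect questioning contrasts with Cohen's h effect sizes, and fits a
    misclassification-adjusted logistic regression by maximum likelihood with
    Wald inference, AIC-based stepwise selection and a Pearson goodness-of-fit
    statistic. A synthetic-cohort simulator emulating a prison survey of 792
    inmates makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
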