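Package: netprior
Title: Co-Expression Module Based Target Prioritization for Drug Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate drug-resistance genes by combining
    two-condition differential expression with weighted co-expression
    modules detected on a patient cohort. Modules are scored for
    over-representation of the top differentially expressed genes with an
    exact binomial tail test, and candidate genes are validated on cohort
    survival data via median-split Kaplan-Meier curves, the log-rank test
    and Cox proportional-hazards regression. Includes a latent-factor
    simulator that generates module-structured cohorts, transcript-level
    differential-expression profiles and proportional-hazards survival
    times with known ground truth, so the full pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
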