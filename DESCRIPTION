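Package: trialchain
Title: Simulated Permissioned Ledger for Clinical-Trial Data Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, self-contained simulation of a smart-contract style
    clinical-trial data-management system: a role-gated six-stage trial
    workflow state machine (IND application, trial initiation, patient
    enrollment, monitoring, serious-adverse-event review, analysis and
    reporting), a hash-chained append-only ledger of digitally signed
    transactions with event signalling and full state replay, a
    content-addressed document store for trial documents, randomized arm
    assignment for placebo-controlled, crossover, factorial and
    noninferiority designs, and a scenario runner with synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    openssl,
    jsonlite,
    tibble,
    yaml,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    digest,
    withr
Config/testthat/edition: 3
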