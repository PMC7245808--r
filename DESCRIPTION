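Package: icsrminer
Title: Rule-Based Text Mining for Medication-Error Signal Detection in
    Safety Report Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects a specific insulin medication error -- extraction of
    insulin from a prefilled pen or cartridge by a syringe (EIPPCS) -- in
    the free-text narratives of individual case safety reports (ICSRs).
    Implements three detection methods side by side: a traditional safety
    surveillance workflow (keyword search plus a curated MedDRA
    preferred-term filter), a dictionary-tagging pipeline with negation
    filters and a same-sentence word-proximity rule, and a configurable
    sentence-scope pattern-rule cascade.  Ships the full evaluation
    protocol (recall, precision under two conventions, Cohen's kappa,
    method-overlap analysis, preferred-term frequency profiling and
    false-positive-only term mining) and a deterministic synthetic ICSR
    corpus generator with gold labels, so the whole pipeline is testable
    without access to a proprietary safety database.
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
    stringi,
    stringr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
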