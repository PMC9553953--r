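Package: stringpull
Title: Longitudinal String-Pulling Phenotyping and Motor-Neuron Histology for ALS Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal fine-motor phenotyping of
    SOD1*G93A mice with the string-pulling task. Computes per-session
    behavioral metrics (time pulling, time on hindlimbs, length of string
    pulled) from annotated pull events, aggregates them to weekly averages,
    detects disease onset by baseline z-score deviation (group level) and
    20% own-baseline deviation (animal level), builds extrapolated
    counterfactual weight baselines, runs Sidak-adjusted weekly group
    comparisons, quantifies motor-neuron field densities in motor cortex
    and lumbar ventral horn, and correlates histological loss with
    behavioral decline. Includes a calibrated synthetic cohort generator
    so the full pipeline is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
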