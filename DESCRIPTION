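Package: plasmidcomp
Title: Population Dynamics of Plasmid Fitness-Cost Compensation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary differential equation models of bacterial populations
    in which the fitness cost of a conjugative plasmid is ameliorated by a
    compensatory mutation carried either on the chromosome (chrCM) or on the
    plasmid itself (plaCM). Provides analytical invasion and domination
    thresholds, fixed-point finding with stability classification, phase
    region classification, continuous-flow and serial-transfer simulation,
    end-point conjugation-rate estimators (Simonsen's gamma and a
    growth-rate-corrected extended variant), Malthusian relative-fitness
    calculation with marker correction, and a synthetic-data generator
    emulating overdispersed flow-cytometry competition counts and
    conjugation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
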