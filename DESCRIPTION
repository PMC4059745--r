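Package: metmemo
Title: Metabolic Memory Model of Body Weight and Food Intake in Rats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the coupled dynamics of fat mass, fat-free mass,
    hunger, leptin, glucose, ghrelin, food availability and an adaptive rate
    of energy expenditure in rats under time-varying caloric restriction.
    The rate of energy expenditure carries a distributed memory of past food
    intake (two trailing-average windows), which lets the model explain why
    identical food totals delivered on different temporal patterns produce
    different body weights. Includes feeding-schedule builders, a fixed-step
    compiled integrator with daily food-deposition events, a three-step
    Nelder-Mead least-squares estimation pipeline, rejection-ABC posterior
    summaries for the memory parameters, AIC comparison of memory versus
    constant-expenditure model variants, and a synthetic-cohort generator
    emulating the study design (weekly weighing, daily leftover measurement,
    terminal fat mass).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
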