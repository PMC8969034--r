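Package: mscca
Title: Cost-Consequence Markov Simulation of Treatment Sequencing in
    Relapsing Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An EDSS-based discrete-time Markov cohort model for
    cost-consequence analysis of disease-modifying therapy sequencing in
    relapsing multiple sclerosis. Simulates a patient cohort over integer
    EDSS states 0-9 plus death under configurable treatment sequences
    (immediate high-efficacy therapy, early or late switch, no switch),
    and reports clinical outcomes (EDSS distribution, relapses,
    disability-adjusted life years), informal-care and productivity
    outputs, and discounted societal costs broken down by category.
    Includes a seeded synthetic-input generator emulating the structure
    of published natural-history and cost inputs, one-way (tornado)
    sensitivity analysis, and delimited-file parameter loading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
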