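Package: olfstoch
Title: Stochastic Olfactory Population Codes: Reliability Analysis, Circuit and Learning Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-to-trial variability in third-order
    olfactory population responses (fly mushroom body Kenyon cells and mouse
    piriform cortex). Classifies cells as reliable or unreliable from
    trial-resolved calcium responses, computes odor-pair overlap and
    similarity statistics with Gamma distribution fits, simulates a linear
    rate-firing model of the PN-KC-APL winner-take-all circuit with
    multiplicative noise at six loci, implements an associative-learning
    model of KC-to-MBON synaptic depression quantifying per-cell
    discrimination contributions, and evaluates reliability-class-masked
    odor decoders with a rank-based all-to-all AUC. Includes a seeded
    synthetic-data generator emulating the statistical structure of the
    recordings so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    caret,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
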