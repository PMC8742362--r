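Package: ccident
Title: Identification of Causal Effects in Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study when and how case-control studies identify causal
    effects. Provides a discrete-time structural cohort simulator with
    counterfactual ground truth, exact enumeration of the observed and
    interventional data laws, the classical control-sampling schemes
    (case-base, survivor and risk-set sampling, unmatched or exact
    pair-matched), inverse-probability-weighted exposure-odds estimators for
    intention-to-treat and per-protocol contrasts, and exact
    distribution-level evaluation of each identifying functional so that
    identification results and their failure under assumption violations can
    be verified computationally.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
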