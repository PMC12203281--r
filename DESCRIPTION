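Package: hichds
Title: Explainable Decision Support for Hypertensive Intracerebral Hemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable decision-support pipeline for hypertensive
    intracerebral hemorrhage (HICH). Generates seeded synthetic electronic medical
    records with gold BIO entity annotations and matched gold treatment plans; trains
    configurable neural sequence labelers (dilated-CNN, bidirectional LSTM, and a small
    masked-LM-pretrained transformer encoder, each terminated by a conditional random
    field) for clinical named entity recognition; normalizes extracted mentions against
    a provenance-tagged medical knowledge-graph triple store; maps the normalized
    patient state to a four-branch treatment plan through a weighted, explainable rule
    engine; and evaluates plans with entity-level precision/recall/F1, ROC/AUC, Cohen's
    kappa, and a configurable 100-point plan rubric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
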