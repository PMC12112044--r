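Package: adcgnn
Title: Hybrid Graph Neural Networks for ADC Payload Activity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds attributed molecular graphs from SMILES strings and 3D
    conformers and trains a hybrid message-passing / multi-head graph
    attention / neighborhood-aggregation network for binary bioactivity
    classification of antibody-drug-conjugate (ADC) payloads. Includes
    scaffold-split benchmarking, an eight-metric evaluation protocol,
    ablation-variant and single-architecture baseline factories, an
    attention-based interpretability framework (attention entropy, effective
    heads, SMARTS / Murcko scaffold / BRICS substructure attribution), and a
    synthetic planted-motif task generator so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    bio3d,
    yaml,
    withr
Config/testthat/edition: 3
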