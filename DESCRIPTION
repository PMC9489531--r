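Package: physvoe
Title: Procedural Intuitive-Physics Probes and Object-Centric Violation-of-Expectation Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for studying intuitive-physics learning with the
    violation-of-expectation (VoE) paradigm from developmental psychology. Provides a
    deterministic rigid-body scene simulator and ray-cast renderer that produce short
    RGB videos with per-object segmentation masks and camera tracks; probe factories
    for five physical concepts (continuity, object persistence, unchangeableness,
    solidity, directional inertia) built by a matched-frame splicing construction with
    machine-checkable frame- and pair-matching guarantees; an object-centric slot
    variational autoencoder (perception) and an InteractionLSTM next-step predictor
    over object codes (dynamics), together with parameter-matched flat baselines; and a
    VoE evaluation harness computing pixel-space surprise, relative surprise, accuracy,
    frame-wise curves and seed-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
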