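Package: mindfuse
Title: Attention-Weighted Multimodal Fusion for Mental-Health Phenotyping
Version: 0.1.0
Authors@R: person("Mindfuse", "Developers", role = c("aut", "cre"),
    email = "maintainers@mindfuse.dev")
Description: Toolkit for multimodal behavioural mental-health assessment.
    Extracts time-domain statistical features from face and gait keypoint
    streams (OpenPose output convention) and from speech (short-time energy,
    cepstral pitch, LPC-root formants, 12 MFCCs), fuses the three modality
    feature matrices with softmax attention weights derived from
    dot/cosine/bilinear/scaled-dot similarity, and scores ten binary
    mental-health indicators with a bank of Gaussian-kernel support vector
    machines. Ships a synthetic-cohort generator (source-filter voice,
    label-dependent keypoint motion) so the whole pipeline is testable
    without any external data, plus a modality-ablation evaluation harness
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
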