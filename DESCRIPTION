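Package: bulbarvoice
Title: Phonatory and Time-Frequency Voice Features for Detecting Bulbar
    Involvement in ALS
Version: 0.1.0
Authors@R: person("bulbarvoice", "developers", role = c("aut", "cre"),
    email = "bulbarvoice@example.org")
Description: A reusable pipeline for automatic detection of bulbar involvement
    in amyotrophic lateral sclerosis from sustained-vowel recordings:
    preprocessing (decimation to 8820 Hz, z-scoring, 150 ms mid-phonation
    segment), 15 phonatory-subsystem features (jitter, shimmer,
    harmonics-to-noise ratio, pitch statistics), 35 Cohen-class time-frequency
    features (Choi-Williams distribution, marginal densities, band energies,
    entropies, joint moments), per-comparison MANOVA-style feature screening,
    and a cross-validated classification harness with five supervised models.
    Includes a synthetic sustained-vowel generator with controllable jitter,
    shimmer, harmonics-to-noise ratio and formant structure so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
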