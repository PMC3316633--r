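Package: tdprime
Title: Subliminal Priming of Temporal Discounting: Behavioural Modelling and
    fMRI Decoding Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how subliminal
    reward-cue primes shift hyperbolic temporal discounting and its neural
    encoding. Implements the logistic-hyperbolic choice model with a
    prime-conditional premium on the discount rate, subject-level maximum
    likelihood estimation with nested model comparison and group-level
    premium inference, signal-detection analysis of prime-visibility tests
    with bootstrapped d-prime confidence intervals, a full experimental
    design generator (trial schedules, amount calibration, run packing), a
    synthetic-data generator for choices, visibility responses and 4-D BOLD
    volumes with planted ground-truth effects, univariate parametric GLMs
    with serial orthogonalization and cluster-level family-wise-error
    inference by sign-flip permutation, and FIR-based searchlight decoding
    with leave-one-run-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
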