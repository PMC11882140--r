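Package: ctaphot
Title: Fiber Photometry and Behavioral Analysis for Conditioned Taste
    Aversion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel fiber photometry recorded
    during intraoral infusion paradigms, together with the behavioral
    measures used in conditioned taste aversion (CTA) studies.  Preprocesses
    465/405 nm demodulated fluorescence into session-normalized z-scored
    traces (isosbestic control fit and subtraction, zero-phase Butterworth
    bandpass), aligns trials to infusion onsets and computes per-trial
    infusion-window statistics, quantifies between-condition discriminability
    with an ideal-observer ROC, scores pose-based behavioral reactivity from
    DeepLabCut tracks and two-bottle sucrose preference, and runs the
    repeated-measures statistics used in such studies (paired t, one-way RM
    ANOVA with Greenhouse-Geisser correction and Dunnett post hoc, two-way
    mixed ANOVA with Sidak or Fisher LSD post hocs, linear regression with
    confidence bands).  Includes a synthetic-data generator producing full
    CTA cohorts (photometry, pose, preference) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    multcomp,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
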