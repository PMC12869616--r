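Package: rppashift
Title: Moderated Differential Signaling Analysis for Reverse-Phase Protein Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for reverse-phase protein array (RPPA)
    signaling studies in which a perturbation (such as amyloid-beta exposure)
    modulates a stimulus response (such as acute insulin stimulation).
    Provides probe-by-sample data handling with loading-factor QC and
    context-aware probe filtering; per-contrast PCA replicate-coherence
    diagnostics (silhouette widths on the components explaining 95% of
    variance, two-dimensional Mahalanobis separation); a precision-weighted
    cell-means linear model engine with empirical-Bayes variance moderation
    supporting a mean-variance trend and robust hyperparameter estimation,
    arbitrary contrasts including second-order difference-of-differences
    "shift" contrasts, Benjamini-Hochberg correction and moderated confidence
    intervals; bounded composite effect-size/FDR scores built from
    raised-cosine ramps; invariant-probe inter-batch shift diagnostics using
    exact Wilcoxon signed-rank tests; a rule-based classifier of stimulus
    response modulation (attenuation, reversal, augmentation, saturation);
    and a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    knitr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
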