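Package: nodulecad
Title: Computer-Aided Detection and Diagnosis of Pulmonary Nodules in CT Slices
Version: 0.1.0
Authors@R: person("NoduleCAD", "Developers", role = c("aut", "cre"),
    email = "nodulecad@example.org")
Description: A tested, reusable implementation of a classical lung-nodule
    computer-aided diagnosis (CAD) pipeline for 2D CT slices: denoising
    (mean-shift mode filtering, Gaussian / Perona-Malik / Catte anisotropic
    diffusion) with PSNR, SSIM and Pratt figure-of-merit image-quality
    metrics; adaptive foreground segmentation with hole filling and
    rolling-ball closing; rule-based candidate pruning on shape descriptors;
    hybrid gray-level, shape and GLCM texture feature extraction; Fisher
    linear discriminant (LDA) feature reduction; and a classifier bank
    (RBF-kernel SVM trained by SMO, a rule+SVM hybrid, particle-swarm-optimized
    logistic regression, random forest with majority vote, and naive Bayes /
    KNN / decision tree baselines) with a full evaluation harness (confusion
    metrics, ROC/AUC, split ladders, cross-validation, LDA ablation).
    Synthetic phantom slices with embedded nodules and vessel-like distractors
    make every stage testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
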