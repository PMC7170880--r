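Package: weakeeg
Title: Weakly Supervised Seizure Onset Detection from Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying weak supervision in clip-level seizure onset
    detection from 19-channel scalp EEG. Provides a seeded synthetic EEG
    simulator with known seizure ground truth and a calibrated noisy-annotation
    model, fixed-length clip dataset construction with class balancing,
    hand-engineered spectral/wavelet/connectivity feature baselines, a densely
    connected inception convolutional network trained with Adam, confusion and
    ROC/AUROC metrics with operating-point selection, and occlusion-sensitivity
    saliency maps. All generators and experiments are deterministic given a
    seed, so weak-versus-gold supervision, sample-size scaling, and transfer
    fine-tuning experiments can be reproduced at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    glmnet
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
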