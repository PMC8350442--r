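Package: gazepatchnet
Title: Expertise Classification from Fixation Image-Patch Sequences over 360-Degree Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts raw 250 Hz gaze streams recorded over equirectangular
    360-degree video into sequences of fixation-centered image patches and
    classifies the recording's author into three expertise classes (novice,
    advanced, expert). Implements I-VT velocity-threshold fixation detection on
    the sphere, 224x224 fixation patch extraction with seam-aware wrapping,
    offline patch augmentation (blur, salt-and-pepper, geometric transforms),
    pluggable CNN feature backbones (a truncated GoogLeNet-architecture
    extractor and a fast deterministic toy backbone), a bidirectional LSTM
    sequence classifier trained with Adam and patience-based early stopping,
    and a leave-one-participant-out evaluation protocol with pooled confusion,
    per-class recall and one-vs-rest ROC/AUC. A seeded synthetic-cohort
    generator produces procedural stimuli and class-conditional gaze so the
    whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
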