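Package: facebci
Title: ERP Preprocessing, Time-Frequency Features and nu-SVM Classification
    for an Affective Face Brain-Computer Interface
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for decoding implicit emotional responses to neutral face
    stimuli from multichannel EEG. Implements a standard event-related
    potential (ERP) chain (average reference, zero-phase 1-30 Hz Butterworth
    filtering, epoching, baseline correction, ocular and movement artifact
    rejection, P1/N170 peak and late-window metrics), complex Morlet wavelet
    time-frequency power features, a nu-SVM radial-basis-function classifier
    with one-vs-one voting, leave-one-out (round-robin) cross-validation and
    a kernel-parameter sweep, plus a classifier-triggered face-morphing
    output. A synthetic multi-subject EEG generator with planted
    face-evoked components makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
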