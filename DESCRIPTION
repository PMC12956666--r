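Package: gmdheeg
Title: Self-Organizing GMDH Polynomial Networks for EEG Motor-Task Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for decoding executed motor tasks from
    multichannel EEG. Extracts ten time- and frequency-domain features per
    electrode (band powers, dominant frequency, amplitude statistics),
    classifies eight-class motor tasks with a self-organizing Group Method
    of Data Handling (GMDH) network of quadratic polynomial neurons arranged
    in a decremental eight-layer architecture, and ships a multiclass
    evaluation suite (confusion matrices, Cohen's kappa, macro and weighted
    precision-recall-F1, stratified cross-validation, depth and
    feature-subset ablations), an exact parameter and operation-count
    profiler, and a class-conditional synthetic EEG generator so the whole
    pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    caret,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
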