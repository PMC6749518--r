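Package: fdass
Title: Predicting Depression, Anxiety and Stress Severity from Facial
    Action Unit Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-layer pipeline that maps per-frame Facial Action
    Coding System (FACS) action-unit intensity streams to Depression
    Anxiety Stress Scale (DASS) severity bands. Layer one is a bank of 31
    multiclass support-vector classifiers turning 72 nonrigid facial
    parameters into action-unit intensity levels, together with eye and
    mouth block detection on binary face masks; layer two normalizes the
    levels and accumulates them into a facial matrix emitting one-second
    31x30 windows; layer three is a fully specified feedforward network
    (tanh/sigmoid/sigmoid, Nguyen-Widrow initialization, momentum
    backpropagation minimizing the average absolute relative error)
    whose three outputs are banded into five severity levels. A
    rule-based aggregator turns per-second predictions into a final
    decision, action-unit signature rules shortcut extreme cases, and a
    synthetic-data generator plus leave-one-out evaluation protocols
    make the whole system testable without access to clinical video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
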