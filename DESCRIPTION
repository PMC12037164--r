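Package: silenttrack
Title: Ocular and Neural Tracking of Silent Speech via Multitaper Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how eye movements and neural channels track
    the unheard acoustic envelope of silently presented speech. Implements
    speech-envelope extraction through a cochlear-map filterbank, FFT-based
    resampling, zero-phase FIR preprocessing and fixed-length epoching,
    multitaper (DPSS) spectral estimation, coherence and partial coherence
    between stimulus features and recorded channels, cluster-based permutation
    statistics (dependent-samples t tests and mixed two-by-three ANOVA on
    forward-minus-backward contrasts), blink detection on an ocular channel,
    and a synthetic-cohort generator so that every stage of the pipeline can
    be exercised and validated without original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
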