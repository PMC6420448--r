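Package: wmintrude
Title: Simulation and Analysis of Episodic-Context Intrusions on Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse experiments in which episodic-memory
    context reinstatement intrudes on working-memory maintenance. Generates
    word-context learning designs, free-recall and delayed-nonmatch-to-sample
    (DNMS) trial sequences, synthetic behavioural cohorts, and synthetic BOLD
    runs with category-selective voxel patterns coupled to a latent
    reinstatement trace. Analyses include categorised substitution errors with
    a bootstrap chance null, within-subject z-scored log reaction-time
    contrasts, one-vs-rest L2-regularised logistic decoding of encoding-context
    evidence from localizer-trained patterns, and random-intercept
    mixed-effects models linking trial-wise reinstatement evidence and
    probe-target overlap to reaction times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    glmnet,
    RNifti,
    nlme,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
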