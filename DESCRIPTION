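Package: socialmap
Title: Searchlight Decoding and Representational Similarity Analysis of
    Social-Concept fMRI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for event-related fMRI studies
    of social-concept representation. Generates synthetic experiments with
    known ground truth (2x2 factorial concept designs, jittered event
    schedules, double-gamma BOLD responses with implanted multivoxel
    patterns, sentence-embedding matrices, and behavioral ratings), prepares
    trial-wise classification examples, and runs whole-brain searchlight
    multivoxel pattern analysis with calibrated linear support vector
    classifiers, dummy-classifier chance subtraction, and three
    cross-validation schemes. Group inference uses threshold-free cluster
    enhancement with sign-flip permutations. Representational similarity
    analysis covers model-based searchlight RSA with shuffle-based chance
    maps and noise ceilings, plus encoding-based RSA via leave-one-subject-out
    ridge regression. Behavioral statistics include paired and two-sample t
    tests with effect sizes, Jeffreys-Zellner-Siow Bayes factors, and
    test-retest intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
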