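Package: conseqsim
Title: Simulation and Fitting of Consequence-Based Sequential Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying decision-making in sequential "consequential"
    tasks, where choosing the larger of two offers lowers the mean value of
    the offers on the next trial of the same episode. Provides a generator
    for episode-structured task sessions, a three-layer cognitive agent
    (two-population mean-field attractor dynamics for perceptual choice, a
    double-well attractor process for the intended decision, and a
    reinforcement-comparison rule for strategy learning), behavioral metrics
    (episode performance, optimal-choice probability, visual discrimination,
    reaction-time distributions, learning time), and a sequential
    grid-search fitting pipeline with goodness-of-fit summaries and
    simulate-then-refit parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
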