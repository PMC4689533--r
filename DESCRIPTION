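Package: tailverdict
Title: Discriminating Light- and Heavy-Tailed Distributions by Block
    Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether a univariate series belongs to the domain of
    attraction of the Gaussian law (light tails) or of a non-Gaussian
    alpha-stable law (heavy tails). The series is summed over
    non-overlapping blocks of growing length and the index of stability of
    the block sums is estimated by an iterative characteristic-function
    regression; the behaviour of the estimated index across block lengths,
    summarized with bootstrap box plots, identifies the limiting law.
    Includes exact and inversion-based simulators for stable, tempered
    stable, square Gaussian and Student's t laws, packaged benchmark
    scenarios, and Kolmogorov-Smirnov, Jarque-Bera and Anderson-Darling
    comparison tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
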