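Package: socialfcm
Title: Fuzzy Cognitive Maps for Complex Social Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, weight, and simulate fuzzy cognitive maps (FCMs) of
    complex social systems. Linguistic evidence gathered from empirical
    literature is graded on a five-level ordinal scale, converted to crisp
    signed edge weights with a Mamdani fuzzy inference system (triangular
    memberships, max aggregation, centroid defuzzification), and iterated
    as a discrete dynamical system under trivalent-sign or hyperbolic-tangent
    thresholding with limit-cycle detection. Includes what-if scenario
    simulation, one-at-a-time sensitivity sweeps, degree and closeness
    centrality with inverse-weight distances and a Big-M convention for
    unreachable pairs, synthetic map generators for testing, and a packaged
    14-concept, 31-edge map of the social determinants of homelessness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
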