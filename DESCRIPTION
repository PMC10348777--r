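Package: retriage
Title: Re-Triage Optimality Analysis for Trauma Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the re-triage of seriously injured patients in
    regionalized trauma systems from linked administrative emergency department
    and inpatient discharge records. Provides a synthetic administrative-data
    generator with known ground truth, record deduplication and encounter
    linkage by patient identifier and date adjacency, an audited
    inclusion/exclusion cascade, optimal/suboptimal re-triage labeling,
    rate aggregation over a state/region/agency/center hierarchy,
    hospital-course comparisons (chi-square tests and 2x2 odds ratios),
    mixed-effects logistic regression of suboptimality with random intercepts
    for sending center and year, weighted directed transfer-network graphs,
    and a geospatial search for alternative level I/II destinations under a
    ground/air transport-time rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
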