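Package: ciliotrack
Title: High-Throughput Locomotion Endpoint Analysis for Ciliated Protozoa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-cell centroid tracks exported by video trackers into six
    locomotor endpoints (total distance, average speed, burst count, angular
    velocity, meandering, rotation count) for ciliates such as Tetrahymena,
    with quality-control filtering of broken tracks, nonparametric group
    comparisons (Mann-Whitney, Kruskal-Wallis with Dunn post-hoc),
    log-inhibitor dose-response EC50 estimation, and PCA plus
    correlation-distance average-linkage clustering of treatment behaviour
    profiles. Includes a seedable run-and-tumble swimmer simulator that writes
    tracker-style fixtures with known ground truth, and a pipeline runner with
    a thin command-line interface.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
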