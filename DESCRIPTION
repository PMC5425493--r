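Package: aquaros
Title: Censored-Data Analysis of Arsenic and Uranium in Unregulated Water
    Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for summarising jointly occurring arsenic and uranium in
    unregulated drinking-water sources sampled by heterogeneous surveys with
    multiple laboratory reporting limits.  Implements robust regression on
    order statistics (ROS) for multiply left-censored data, including the
    Hirsch-Stedinger exceedance-probability recursion and Weibull plotting
    positions; maximum-contaminant-level (MCL) exceedance and co-exceedance
    classification; Kendall correlation of co-occurring analytes; a
    Peto-Peto two-group test for censored concentrations; distance-to-mine
    proximity partitions and distance-concentration profiles; a synthetic
    multi-survey generator for end-to-end validation; and a pipeline that
    emits summary tables, profiles and GeoJSON maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
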