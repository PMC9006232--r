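Package: cropwatch
Title: Comparing Camera-Trap, Guard and Researcher Records of Crop-Foraging Wildlife
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for evaluating low-cost observation methods against
    direct researcher observation in monitoring wildlife incursions into crop
    fields. Simulates ground-truth crop-foraging events by diurnal primates
    (chacma baboons and vervet monkeys) and their imperfect detection by
    motion-triggered field-edge cameras, a crop guard, and researchers in a
    hide; delineates independent crop-foraging events with a pooled 30-minute
    temporal-independence window for photographs and a 1-minute empty-field
    rule for observers; aggregates daily measures to matched-day means over
    ten-day periods; fits the method-agreement linear regressions; and runs an
    exhaustive camera-subset survey-design simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    lubridate,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
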