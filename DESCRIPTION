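Package: wearcpet
Title: Smartwatch Heart Rate and Step Processing with Cardiopulmonary
    Exercise Test Fitness Indices and Association Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processes raw smartwatch heart-rate and step streams into
    per-participant nonactive heart rate and valid daily-step summaries
    (motion-context inference from recording intervals and hourly step
    counts, person-day wear and step filters), derives six fitness
    indices from breath-by-breath cardiopulmonary exercise testing data
    (peak VO2, percent-predicted peak VO2, VO2 at the ventilatory
    anaerobic threshold via the V-slope method, VE/VCO2 nadir,
    percent-predicted maximum heart rate, and the systolic blood
    pressure to workload slope), and runs a multivariable linear
    association battery with Benjamini-Hochberg false discovery rate
    control, effect-modification, and sensitivity analyses. A synthetic
    cohort generator with known ground truth makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
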