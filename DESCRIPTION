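Package: barrettsCEA
Title: Surveillance Statistics and Cost-Utility Modelling for Low-Grade
    Dysplasia in Barrett's Esophagus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Person-time progression statistics for Barrett's esophagus
    surveillance cohorts (crude proportions, exact Poisson incidence-rate
    confidence intervals, exact conditional incidence-rate-ratio intervals),
    a synthetic patient-level cohort generator, and a discrete-time Markov
    cohort cost-utility model comparing endoscopic surveillance against
    radiofrequency-ablation strategies for low-grade dysplasia: staged
    calibration of transition probabilities to person-year targets,
    incremental cost-effectiveness ratios, net monetary benefit and
    efficiency frontiers, one-way (tornado) sensitivity analysis with
    threshold finding, probabilistic sensitivity analysis with gamma/beta
    parameter draws, and cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
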