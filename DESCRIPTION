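Package: pillowpart
Title: Partitioned Head and Neck Support Modeling from Body Pressure
    Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for constructing a partitioned support model of the head
    and neck from body-pressure-distribution recordings on a sensor mat.
    Computes the standard pressure comfort indices (average pressure, peak
    pressure, maximum and mean pressure gradient), builds an approximate
    ideal pressure-distribution matrix from the highest-comfort trials,
    segments it into anatomically named support partitions by fuzzy c-means
    clustering of the pressure values, derives per-partition pressure
    sensitivity weights from expert pairwise comparisons by a fuzzy analytic
    hierarchy process, scores weighted comfort, and translates per-partition
    support requirements into a perforated-foam material design (equivalent
    stiffness and a staggered pore-array layout). A seeded synthetic-data
    module emulates pressure-mat cohorts, expert panels, anthropometric
    contour nodes, and stiffness calibrations so the whole pipeline is
    testable without human-subject data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
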