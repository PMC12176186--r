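Package: pdxscreen
Title: Multi-Measure, Multi-Laboratory Drug Screening for PDX Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical evaluation of candidate anti-cancer drugs in
    patient-derived xenograft (PDX) trials replicated across laboratories.
    Converts longitudinal tumor volumes into empirical tumor growth
    trajectories, computes five per-mouse growth measures (day-21 percent
    volume change, area under the trajectory, normalized full-trajectory
    area, log tumor-growth-inhibition ratio, and progression-free survival
    to a fold-increase threshold) with their two-arm test statistics,
    combines laboratory p-values by Fisher's method, corrects across
    measures with Storey's step-down q-values, assembles the resulting
    basis table, applies four drug-screening decision rules (SMSL, SMNL,
    NMSL, NMNL), and estimates sensitivity, specificity and accuracy
    distributions by stratified bootstrap resampling of mice. Includes a
    synthetic multi-laboratory trial generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
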