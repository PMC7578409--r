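Package: fpaccel
Title: Accelerated-Transition Targets for Family Planning Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts demand-satisfied (DS) benchmarks for modern
    contraception, such as 75 percent of demand satisfied by 2030, into
    country-specific modern contraceptive prevalence (mCPR) targets with
    the accelerated-transition (AT) method, and compares them with the
    demand-based (DB) comparator. Includes a simplified deterministic
    logistic transition model that fits sparse survey series of modern use,
    traditional use and unmet need among married or in-union women and
    projects business-as-usual trajectories; a synthetic-survey generator
    with known ground truth for validation; and table readers, writers and
    summary statistics for assessment reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, graphics
Suggests: testthat (>= 3.0.0), jsonlite, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
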