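Package: npcholm
Title: Nonparametric Combination of Permutation Tests with Holm Step-Down
    Adjustment for Two-Group Clinical Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-group comparison of mixed numeric and categorical outcomes by
    permutation inference. Per-variable partial permutation tests (absolute
    difference of means for numeric variables, likelihood-ratio G statistic
    for categorical variables) are estimated by Conditional Monte Carlo or
    exact enumeration on a shared permutation stream, combined into a single
    global test by the NonParametric Combination (NPC) method with Fisher,
    Liptak or Tippett combining functions, and adjusted for multiplicity by
    the Bonferroni-Holm sequentially rejective step-down procedure. Includes
    a synthetic-cohort generator emulating a published inflammatory bowel
    disease cohort (Crohn's disease vs ulcerative colitis, 1722 patients, 22
    variables) so the full pipeline runs without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
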