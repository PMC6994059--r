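Package: pfda
Title: Precision-Fed Rooster Digestibility and Metabolizable Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational chain for precision-fed cecectomized rooster
    digestibility assays of complete pet foods: proximate-composition
    accounting on a dry-matter basis with nitrogen-free extract by
    difference, nitrogen-corrected true metabolizable energy (TMEn) with
    fasted-bird endogenous correction, true/standardized nutrient and amino
    acid digestibility, three metabolizable-energy prediction systems
    (Atwater, modified Atwater, NRC fiber-based chain) with comparison
    against TMEn, the study-level statistics (one-way ANOVA for a completely
    randomized design, pooled SEM, Tukey multiple comparisons, compact
    letter display), and a synthetic assay generator with known ground
    truth so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
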