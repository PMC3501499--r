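Package: rodiso
Title: Stable Isotope Analysis of Modern Rodent Communities
Version: 0.1.0
Authors@R: person("Rodiso", "Maintainers", email = "maintainers@rodiso.org",
    role = c("aut", "cre"))
Description: Tools for oxygen and carbon stable isotope analysis of small-mammal
    (rodent) community bioapatite data: carbonate-phosphate delta18O offset
    estimation, inversion of published phosphate-to-drinking-water calibration
    equations, delta13C diet reconstruction with C3/C4 end-member mixing,
    per-species and per-tissue community statistics (ANOVA, Tukey HSD,
    Kruskal-Wallis, paired tissue offsets, outlier flagging), an empirical
    bootstrap minimum-sample-size procedure, and a seasonally explicit
    synthetic rodent-community generator for testing the whole pipeline
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
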