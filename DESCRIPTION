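Package: metalloscreen
Title: Analytics for Combinatorial Metal-Complex Libraries Screened
    Direct-to-Biology
Version: 0.1.0
Authors@R:
    person("Metalloscreen", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: End-to-end analytics for high-throughput "click-to-metal-complex"
    screening campaigns. Enumerates bidentate pyridyl-triazole ligand libraries
    from amine and alkyne building blocks, assembles metal-complex compositions
    against five organometallic scaffolds, computes monoisotopic masses,
    isotope-pattern envelopes and expected ion species, automates LC-MS
    characterization (target-ion extracted-ion chromatograms, UV peak
    integration, conversion percent), analyses broth-microdilution plates (MIC
    calling, percent-of-control, toxicity flags), fits four-parameter-logistic
    dose-response curves (CC50, HC10) and therapeutic indices, summarizes
    transfer-hydrogenation kinetics, and models structure-activity
    relationships with a fixed-width binary fingerprint and a linear
    support-vector machine under stratified cross-validation. Seeded synthetic
    data generators emulate every input with ground truth attached.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
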