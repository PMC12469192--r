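Package: aivive
Title: GAN-Based In Vitro to In Vivo Extrapolation of Toxicogenomic
    Expression Profiles with Module-Guided Local Optimizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates in vitro rat-liver transcriptomic profiles into
    synthetic in vivo profiles with a cycle-consistent generative
    adversarial network conditioned on experiment labels (system, dose,
    time, replicate), then refines biologically important co-expression
    modules with small per-module neural refiners that are accepted only
    when they improve held-out reconstruction. Ships a synthetic
    TG-GATEs-style study generator with known ground truth, similarity
    evaluation against baseline and replicate controls (cosine, RMSE,
    MAPE, Welch's t-test), differential-expression and pathway
    over-representation comparison, adverse-outcome-pathway gene
    percent-error analysis, and a gradient-boosted necrosis classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
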