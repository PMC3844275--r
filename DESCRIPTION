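Package: lhpriming
Title: Two-Pathway Model of GnRH-Induced LH Secretion with Self-Priming
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and weighted nonlinear least-squares fitting of a
    two-pathway linear compartment model of luteinising hormone (LH)
    secretion from pituitary gonadotrophs stimulated by pulses of
    gonadotropin-releasing hormone (GnRH). A fast pathway drives an acute
    LH surge through a single rate-limiting intermediate; a slow pathway
    synthesises, after a delay, a protein that synergises with the fast
    pathway, producing the shoulder on the declining phase of a surge,
    self-priming of subsequent surges, and the biphasic response to
    constant GnRH. Includes an oxytocin augmentation term, a synthetic
    perifusion-data generator with replicate Gaussian noise, Monte-Carlo
    confidence-interval coverage checks, and predictive scenario
    simulations (altered pulse spacing, protein-synthesis inhibition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
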