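Package: mgturing
Title: Multigenerational Turing Model of Diploid Petal Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Activator-inhibitor reaction-diffusion modelling of anthocyanin
    petal patterning across generations of a diploid cross, as in hybrid
    monkeyflower (Mimulus). Per-allele rate constants and a 16-entry table of
    competitive Hill binding constants are propagated by Mendelian inheritance
    to build genotype-specific reaction-diffusion systems; linear stability
    analysis locates the Turing bifurcation in the inhibitor-to-activator
    diffusion ratio, a seeded random search finds admissible parameter sets
    (Turing-stable parents, Turing-unstable F1 hybrid), an
    alternating-direction implicit solver integrates the fields on a 2D
    domain, and simulated petals are classified as patterned or solid. The
    symmetric-parents limit exposes the trans/cis binding-efficacy mechanism
    for transgressive hybrid phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
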