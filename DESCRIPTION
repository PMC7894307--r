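Package: beetlescape
Title: Desk-Scale Simulation of Bark Beetle Disturbance Feedbacks in
    Mixed Mountain Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort-based forest landscape simulator coupled to an annual
    Ips typographus outbreak model (phenology, winter mortality,
    windthrow-fuelled population growth, dispersal, host colonization
    against tree defence), eight structural and compositional diversity
    indicators computed on a 100-m grid (Shannon alpha/beta diversity of
    height and diameter classes, canopy cover, rumple index, spruce
    proportion, host aggregation), a factorial climate by disturbance
    scenario engine with paired disturbed/undisturbed replicates, and a
    random-forest counterfactual analysis that quantifies whether
    disturbance-mediated changes in forest structure and composition
    amplify or dampen future bark beetle activity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
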