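Package: mycodiv
Title: Design and Analysis of Tree Diversity by Mycorrhizal Type Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and analysing tree diversity experiments that
    cross species richness with mycorrhizal association type (arbuscular
    vs. ectomycorrhizal). Provides trait-based selection of matched species
    pools via Gower dissimilarity and Rao's quadratic entropy, generation of
    balanced species compositions and spatially constrained plot
    randomizations, a resource-niche simulator producing tree-level diameter
    time series, additive partitioning of mixture productivity into net
    biodiversity, complementarity and selection effects, and mixed-model
    inference with bootstrap confidence intervals and marginal/conditional R2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
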