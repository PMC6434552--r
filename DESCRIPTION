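Package: copulacomm
Title: Gaussian Copula Models for Multivariate Ecological Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pathway for multivariate analysis of ecological communities
    recorded as counts of species abundances. Individual species are
    characterized by flexible discrete marginal distributions (Poisson,
    zero-inflated Poisson, negative binomial, zero-inflated negative
    binomial) selected by AICc; pairwise associations are screened with a
    permutation test of an index of association that excludes joint
    absences; significant associations are modeled with a Gaussian copula
    whose correlation matrix is estimated by Monte Carlo expectation
    maximization over latent hyper-rectangles. Fully parameterized copula
    models simulate realistic community data under null or alternative
    hypotheses, feeding dissimilarity-based ordination of group-centroid
    distributions, model-based PERMANOVA inference, canonical analysis of
    principal coordinates (CAP), and multinomial-mixture power curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    vegan,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
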