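Package: twinbayes
Title: Bayesian Estimation of Casewise Twin Concordance Rates for Rare Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the prevalence and the casewise concordance rates of a
    dichotomous trait from monozygotic and dizygotic twin-pair counts. The
    data for each zygosity group are the numbers of pairs with both twins
    affected, one twin affected, and neither affected, modelled with a
    multinomial likelihood parametrized by the population prevalence and a
    label-invariant within-pair dependence difference per zygosity.
    Estimation is fully Bayesian: Beta and truncated scaled-Beta priors, a
    Laplace approximation for the posterior mode and covariance, and a
    random-walk Metropolis-Hastings sampler on logit-transformed parameters.
    Posterior means, standard deviations, medians, and highest posterior
    density intervals are reported for the prevalence, the concordance
    rates, and their contrasts. Informative priors can be built from
    prevalence studies, and historical twin studies can be pooled by summing
    count vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
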