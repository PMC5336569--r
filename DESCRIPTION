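Package: thermometab
Title: Thermal Reaction Norms of the Drosophila Metabolome from 1H NMR
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 1H NMR metabolomics of Drosophila
    melanogaster reared across its full developmental temperature range.
    Provides a synthetic spectrum and phenotype generator with planted
    reaction-norm ground truth, spectral preprocessing (TSP referencing,
    segment-wise alignment, water/edge trimming, total-intensity
    normalization, Pareto scaling), multivariate chemometrics (PCA with
    target rotation into linear and U-shape components, OPLS and OPLS-DA
    with leave-condition-out Q2, Ward clustering of condition scores),
    metabolite-level correlation screening with sequential Bonferroni
    correction and reaction-norm classification, sex-difference spectral
    analysis, and the four functional-phenotype models (thermal limits,
    egg-to-adult viability, developmental time).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
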