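Package: scatrisk
Title: Scat-Based Spatial Predation Risk Surfaces for Ungulate Prey
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds spatial predation-risk maps for elk from carnivore scat
    surveys. Scat locations along detection-dog transects are modelled with
    exponential resource selection functions (use/available logistic designs),
    weighted by predator abundance density surfaces, and multiplied by models
    of elk occurrence in scats to give per-predator and total risk surfaces,
    which are benchmarked against a matched conditional-logistic kill-site
    model. A synthetic landscape and survey generator with known coefficient
    sets makes every stage testable without field data: Gaussian random field
    covariate rasters, linear features, transect campaigns, scat deposition
    and contents, elk GPS relocations from a utilization surface, and kill
    sites from the combined risk surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'raster.R'
    'landscape.R'
    'covariates.R'
    'survey.R'
    'models.R'
    'ruf.R'
    'risk.R'
    'killsite.R'
    'validation.R'
    'fixtures.R'
    'pipeline.R'
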