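Package: speedmix
Title: Encoding and Decoding of Multiple Motion Speeds in Neural Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing how populations of speed-tuned visual
    neurons (such as those in macaque area MT) represent two simultaneously
    presented motion speeds. Implements regression-based estimation of
    component response weights, a divisive-normalization model whose
    component weights are set by a speed-tuned weighting pool, construction
    of normalized pseudo-population responses with cubic smoothing splines,
    cross-validated linear-classifier discrimination of bi-speed versus
    single-speed responses, and a constrained decoder that extracts a one-
    or two-speed probability distribution from a population response.
    Includes a synthetic-data generator that emulates the statistical
    structure of recorded MT populations so the full pipeline can be
    exercised without neural recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
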