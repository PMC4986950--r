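Package: ffmr
Title: Mechanistic Forest Flammability Modelling from Leaf Traits and Stand Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A time-stepped, trait-driven simulator of flame propagation in
    multi-strata eucalypt forests. Leaf morphology, moisture and chemistry
    drive leaf-scale ignitability, combustibility and sustainability
    sub-models; a convective plume couples burning (donor) foliage to unburnt
    (receiver) foliage through crown geometry, wind-tilted flame angles and
    overstorey wind sheltering via leaf area index. The package predicts
    stand-level flame height from a surface litter pilot fire upward through
    near-surface, elevated, midstorey and canopy strata, implements the
    three-treatment validation framework (surface fuel only; plus stand
    structure; plus species leaf traits) with interval-based error statistics,
    and attributes treatment differences to mechanisms with an ensemble
    cross-validated LASSO analysis. A seeded synthetic-stand generator makes
    the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
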