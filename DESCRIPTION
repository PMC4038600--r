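Package: morphorates
Title: Phylogenetic Morphospace Analysis and Morphological Rate Decoupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of multivariate linear morphometrics on a
    molecular phylogeny. Provides isometric size correction (Burnaby back
    projection and regression residuals), principal-component ordination with
    phylomorphospace projection, permutation-based group tests (PERMANOVA,
    Mantel) and discriminant reassignment, phylogenetic signal statistics
    (Blomberg's K with clade-subsampling sensitivity, PGLS with Pagel's
    lambda), least-squares estimation of morphometric branch lengths with
    rate-ratio outlier screening, and multivariate standardized independent
    contrasts. A synthetic-data module simulates trees and trait tables with
    the covariance structure the analyses assume, so the whole pipeline is
    testable without specimen data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    phytools,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    jsonlite
Config/testthat/edition: 3
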