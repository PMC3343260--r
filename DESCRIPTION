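Package: twinace
Title: Bivariate Liability-Threshold ACE Models for Disease-Endophenotype Twin Data
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Tools for decomposing the association between a dichotomous
    disorder and a continuous endophenotype into genetic and environmental
    components using monozygotic and dizygotic twin pairs.  Implements the
    liability-threshold model with constrained polychoric twin correlations,
    full-information maximum likelihood over ordinal pair tables, a bivariate
    Cholesky ACE decomposition with the disorder side fixed to external
    population estimates (ascertainment correction), profile-likelihood
    confidence intervals, and a synthetic twin-cohort simulator that
    reproduces disease-based ascertainment designs for validation by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
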