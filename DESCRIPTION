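Package: mpratio
Title: Mixture Toxicity Ratio Testing for Suspended Particulates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disentangling the toxicity of a test particulate (such as
    a microplastic) from that of a reference particulate (such as kaolin clay)
    in suspension mixtures. Implements the full data-evaluation workflow for
    ratio-design acute immobilization bioassays: validation of replicate-level
    mortality records, Abbott's correction for control mortality, constrained
    three-parameter logistic dose-response fits with LC50/LC10 estimates and
    confidence intervals, balanced replicated subsampling of over-replicated
    treatments, one-phase exponential-decay modelling of LCx against the test
    particle's mass fraction, and derivation of the no-observed-effect
    concentration (NOEC) and the no-effect percentage of microplastic
    (NOE%MP). A synthetic bioassay generator supports parameter-recovery and
    design-power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
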