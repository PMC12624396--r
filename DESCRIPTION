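Package: c4dyn
Title: Dynamics of C4 Photosynthesis During Irradiance Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for maize C4 photosynthesis during sudden
    irradiance transitions: dynamic (non-steady-state) correction of open
    chamber gas-exchange records, kinetic decomposition of multiphasic net
    assimilation responses, stoichiometry-weighted metabolite pool accounting
    for the Calvin-Benson cycle, intercellular energy shuttle and CO2
    concentrating mechanism, phase-integrated carbon gain/loss budgets, and
    trajectory-level multivariate statistics. Includes a synthetic-data
    generator that emulates the kinetic and replicate-noise structure of
    moderate-to-low and low-to-moderate light transition experiments so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
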