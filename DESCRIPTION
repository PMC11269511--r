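Package: demotox
Title: Demographic Ecotoxicology of Biocontrol Agents: Two-Sex Life Tables,
    Bootstrap Inference, and IOBC Toxicity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing lethal and sublethal side effects of
    pesticides on beneficial arthropods such as phytoseiid predatory mites.
    Implements the age-stage two-sex life table (survivorship lx, fecundity
    mx, net reproductive rate R0, intrinsic rate of increase r, finite rate
    of increase lambda, and mean generation time T), bootstrap standard
    errors and paired bootstrap tests for cohort statistics, corrected
    mortality (Henderson-Tilton and Abbott forms), the reduction coefficient
    Ex combining mortality with fecundity, fertility and longevity ratios,
    IOBC toxicity classification for laboratory and extended-laboratory
    schemes, and persistence classification of aged pesticide residues. A
    stochastic individual-based cohort generator with known analytic
    schedules supports validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
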