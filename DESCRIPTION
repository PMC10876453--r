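Package: orchidscore
Title: Occurrence-Based Healthy Dietary Diversity (ORCHID) Scoring for Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the ORCHID score, an occurrence-based healthy dietary
    diversity score for older adults built from 24-hour dietary recall
    declarations and food propensity questionnaire (FPQ) frequencies.
    Provides recipe disaggregation of complex dishes, half-standard-portion
    daily gating of consumption occurrences, random-forest imputation of
    missing FPQ responses, the positive and threshold component rating
    formulas, companion diet-quality measures (solid energy density, mean
    adequacy ratio, PANDiet), a survey-weighted construct-validity analysis
    battery, and a seeded synthetic dietary-survey generator so the whole
    pipeline is testable without external microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
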