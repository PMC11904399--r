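Package: ffqkit
Title: Nutrient Intakes and Dietary Patterns from an Unquantified Food
    Frequency Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives daily nutrient intakes from coded responses to a
    pregnancy food frequency questionnaire: five-category weekly frequency
    recoding, portion-weighted summation over a food-composition table with
    nutrient-specific alternate portion lists, daily-basics resolution
    (bread, milk, fats, sugar, soft drinks), plausibility exclusion rules,
    closed-form fish n-3/EPA/DHA and caffeine estimators, dietary-pattern
    scoring by varimax-rotated principal components, misreporter screening
    against predicted energy requirements, and energy standardisation.
    Includes a synthetic-cohort generator with known latent diet structure
    so the whole pipeline is testable without access-controlled cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
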