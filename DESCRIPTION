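Package: lifeineq
Title: Length-of-Life Inequality from Relational Model Life Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models group-specific abridged life tables with the Brass logit
    (and modified-logit) relational system from under-five (5q0) and adult
    (45q15) mortality inputs, estimates group adult mortality from national
    rates and under-five mortality ratios, and quantifies length-of-life
    inequality within groups (Gini health index, absolute length-of-life
    inequality) and between socioeconomically ranked groups (concentration
    index, absolute difference in life expectancy). Includes a synthetic
    scenario generator with known ground truth for validating the full
    pipeline, motivated by settings such as Ethiopia where vital
    registration is incomplete and only summary mortality rates by wealth
    quintile, gender and residence are available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
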