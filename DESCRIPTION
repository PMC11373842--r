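Package: foodprintr
Title: Agricultural Resource Footprints and Carrying Capacity of Diet Patterns
Version: 1.0.0
Authors@R:
    person("Foodprintr", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A biophysical simulation of the food system that converts diet
    patterns (per-capita or individual-level daily servings of 22 food
    groups) backwards through the food chain into agricultural commodity
    requirements and then into land, fertilizer-nutrient, pesticide, and
    irrigation-water use. Supports open and closed trade systems, a
    multiuse-crop coproduct ledger that prevents double counting of land,
    grazing-land reallocation onto cropland, and carrying-capacity
    estimation from a fixed land base. Includes a validated parameter-set
    container with delimited-table serialization, survey batch processing
    with analytic exclusion rules, seeded synthetic fixtures, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
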