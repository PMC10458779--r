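Package: tubertrace
Title: Potato Tuber Mass from Chamber CO2 Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts measured carbon dioxide dynamics in a sealed (or
    controllably leaky) cultivation chamber into potato tuber mass through
    the stoichiometry of starch synthesis from CO2. Provides a chemical
    formula parser and exact rational reaction algebra used to derive the
    net starch-synthesis reaction, gas-state unit conversions between mole
    fraction, number concentration and mass concentration, sealed- and
    unsealed-chamber tuber-mass estimators with an integral leaf-flux
    variant, a forward chamber simulator with ground truth for closed-loop
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
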