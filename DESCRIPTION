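Package: radioyield
Title: Thick-Target Activation Yields and Radiopharmaceutical Quality Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models accelerator production of radionuclides on thick targets:
    beam energy degradation through the target from tabulated mass stopping
    powers, the thick-target activation yield integral over tabulated
    excitation functions, co-production inventories across all open reaction
    channels with decay correction to end of bombardment, and comparison of
    modelled to measured yields. Companion quality-control calculations cover
    specific and molar activity with their carrier-free ceilings, apparent
    molar activity from chelator titration series, radiochemical labeling
    yield from radio-TLC traces, and SUV/SUVR quantification from
    region-of-interest tables. A deterministic synthetic-data generator
    produces every input format with known ground truth for end-to-end
    testing.
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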