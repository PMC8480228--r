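Package: ch4margin
Title: Pulse-Response Emulation of Warming from Livestock Methane and Net CO2 Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-complexity climate-carbon-cycle emulator and analysis
    toolkit for quantifying the contribution of livestock methane emissions to
    warming under stringent temperature goals. Converts annual net CO2 and
    livestock CH4 emission pathways into concentration, radiative-forcing and
    temperature anomalies using an impulse-response carbon cycle, a single-box
    methane model and a two-mode thermal response; decomposes warming into
    legacy (pre-2020) and marginal (future-emission) components; inverts
    temperature-matched CO2 pathways to express unmitigated livestock methane
    as a remaining-carbon-budget cost; finds the methane decline rate that
    stabilizes methane-induced warming; and evaluates mitigation potentials of
    emerging livestock technologies from a system-by-income emissions table.
    Includes deterministic generators for stylized 1.5 degree-consistent and
    business-as-usual scenario inputs in IAMC-style CSV format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
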