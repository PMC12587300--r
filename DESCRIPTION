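Package: fecolumn
Title: Natural-Attenuation Audit for Iron-Reducing Column Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing natural attenuation of monoaromatic
    hydrocarbons in iron-rich sandy aquifer columns. Implements the design
    hydraulics of a laboratory flow-through column (Darcy flux, seepage
    velocity, hydraulic retention time, pumping rate), a one-dimensional
    advection-dispersion-sorption-reaction simulator of treatment and
    sterile-control columns with dual-Monod iron-reducing toluene
    biodegradation, electron-balance conversion of reduced iron to
    toluene-equivalents (36 electrons per toluene for complete
    mineralization), solid-phase versus dissolved Fe(II) mass accounting
    and partition fractions, toluene mass balance, and groundwater
    quality threshold (GB14848) exceedance mapping over the port-by-day
    monitoring grid. Includes long-format CSV data contracts with
    validation, a YAML-configured pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
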