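Package: landpop
Title: Malthusian and Boserupian System-Dynamics Models of Population and
    Land Use for a Rural Region
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete annual system-dynamics simulation of the coupled
    population, technology, land-use, livestock and two-sector income
    dynamics of a rural alpine region over 1961-2011.  Two model variants
    implement opposing theories of agrarian change: a Malthusian variant
    with exogenous, linearly growing yields, and a Boserupian variant in
    which population density drives the adoption of technology (proxied by
    the ratio of non-agricultural to agricultural income), which in turn
    raises yields and depresses fertility.  Two out-migration scenarios
    (income-driven and structural-change-driven) complete a four-run
    comparison matrix.  Includes a seeded synthetic driver generator
    emulating the statistical structure of the national input series, land
    stock-flow accounting with irreversible forest succession, cohort
    demography, and a trajectory-deviation evaluation stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
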