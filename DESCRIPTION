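Package: loopstate
Title: Conformational Coordinates, Free-Energy Profiles, and Ionic-Strength
    Analysis for the DHFR M20 Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how solution ionic strength modulates the
    conformation of the M20 active-site loop of Escherichia coli
    dihydrofolate reductase. Provides a scalar conformational coordinate
    built from loop and binding-site anchor geometry, free-energy profiles
    by Boltzmann inversion and by the weighted histogram analysis method
    (WHAM) over unbiased and umbrella-biased samples, distance-dependent
    electrostatic potentials around the loop from ion and solvent particle
    summations and from radial distribution functions, ionic-strength and
    box-composition utilities for 1:1 and 2:1 salts, a survey stage
    correlating crystallization ionic strength with observed loop
    conformers, and seed-deterministic synthetic-data generators that make
    every stage testable without molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
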