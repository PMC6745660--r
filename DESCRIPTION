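Package: ternlight
Title: Light-Level Geolocation and Migration Phenology for Long-Distance Seabird Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing archival light-level geolocator data from
    long-distance migrants such as the arctic tern. Implements the threshold
    twilight method (sunrise/sunset detection, breeding-site sun-angle
    calibration, longitude from local noon or midnight, latitude from day
    length with equinox masking and elevated-threshold handling of the
    Antarctic polar day), daily track assembly with longitude unwrapping,
    detection of migration phenology events, stopovers and
    Antarctic-Convergence displacements, rhumb-line (loxodrome) route
    distances and travel speeds over waypoint chains, and a grand-median /
    Fisher exact comparison of nonbreeding longitudes between populations.
    Includes a synthetic-data module that simulates logger light series along
    waypoint-interpolated migration trajectories, including equinox ambiguity
    and polar-day light regimes, so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
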