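Package: dolinekit
Title: Tension Buffering by Curved Membrane Protein Domains and dSTORM
    Cluster Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models membrane tension buffering by protein-coated spherical-cap
    domains: exact cap geometry and Helfrich-type mechanical energy with
    spontaneous curvature, a quasi-static two-state model of a single domain
    (continuous unfolding versus bistable, hysteretic snapping), and a
    thermodynamic ensemble model that minimizes free energy over domain
    density, size and shape at fixed tension and protein coverage. Also
    provides the matching single-molecule localization (dSTORM) cluster
    pipeline (filtering, consecutive-blink merging, global density
    homogenization, DBSCAN, convex-hull and Feret measurements, size-stratum
    summaries), biophysical measurement utilities (spherical Hertz AFM
    fitting, Laurdan generalized polarization, optical-stretcher axial
    strain), and synthetic-data generators so every analysis is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
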