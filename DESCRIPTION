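Package: nfkbcoupler
Title: Coupling of the Canonical and Noncanonical NF-kB Pathways Under
    Translational Delays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic delay-differential-equation model of the coupled
    canonical/noncanonical NF-kB signalling network in airway epithelial
    cells, with discrete translational delays for TRAF1 and NF-kB2/p100.
    Implements the coupling-interval statistic (time from TNF stimulation to
    threshold p52 formation), single-axis and combinatorial translational
    delay scans on a 15-minute lattice, regime classification of delay
    combinations, deterministic calibration, and delay recovery from noisy
    p52 time courses.  A companion qPCR expression pipeline provides
    delta-delta-Ct relative quantification, row-wise Z-score transformation,
    average-linkage clustered image maps with explicit missing-data
    handling, genomic-DNA standard curves and ChIP fold-enrichment
    arithmetic, together with seeded synthetic-data generators that emulate
    the study's Ct tables, dilution series and p52 trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
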