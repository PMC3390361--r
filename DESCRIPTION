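Package: whiskr
Title: Tracing, Identity Tracking and Kinematics of Rodent Whiskers in
    High-Speed Video
Version: 0.1.0
Authors@R:
    person("Nadia", "Kovak", email = "nkovak@example.org",
           role = c("aut", "cre"))
Description: Fully automated analysis of high-speed videos of head-fixed
    rodents trimmed to a single row of whiskers. Each frame is traced
    independently: candidate initiation sites are found with a local
    eccentricity detector, whisker backbones are grown to sub-pixel
    precision with a bank of oriented matched line detectors, and
    occlusions (pole contacts, whisker crossings) are bridged by linear
    gap jumping. Traced curves are then assigned persistent identities
    with a hidden Markov model over anterior-posterior ordered labels,
    trained from the video itself via a length-threshold heuristic and
    shape/motion histograms, and propagated across frames in confidence
    order. Downstream measurement yields angle at base, windowed
    curvature, follicle position and whisker-pole contact geometry. A
    ground-truthed synthetic video generator, file readers/writers and a
    command line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
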