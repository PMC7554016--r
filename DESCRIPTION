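Package: flyvis
Title: Drosophila Motion-Vision Pathway Model for Direction Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A feed-forward computational model of the Drosophila motion-vision
    pathways that decodes the principal direction of a foreground object
    translating against cluttered moving backgrounds. The pipeline runs from
    photoreceptor temporal differencing, through a variant
    difference-of-Gaussians (vDoG) centre-surround stage, ON/OFF half-wave
    splitting and fast-depolarising slow-repolarising (FDSR) adaptation, to
    ensembles of two-quadrant delay-and-correlate detectors (T4/T5) tuned to
    the four cardinal directions, pooled by opponent wide-field HS/VS systems
    with a sigmoid output. Includes a deterministic synthetic stimulus
    generator (translating bars and squares, approaching/receding discs,
    procedurally cluttered moving backgrounds) and scripted experiment suites
    for direction decoding, speed tuning, ensemble-size, ablation and
    target-size studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
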