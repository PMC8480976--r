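Package: mvsgaze
Title: Oculomotor Analysis of Magnetic Vestibular Stimulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 50 Hz video-oculography recorded while
    subjects lie inside and outside the static field of a 3T MRI scanner.
    The static field stimulates the labyrinth (magneto-hydrodynamic
    vestibular stimulation, MVS), inducing a horizontal nystagmus and
    neglect-like rightward biases of overt spatial attention. The package
    covers low-pass filtering, five-point gaze calibration, tonic offset
    compensation, blink exclusion, velocity-threshold saccade detection,
    de-saccaded slow-phase velocity estimation, subjective straight-ahead
    and visual-search center measures, and the within-subject statistics
    used to compare them across scanner phases (paired contrasts with a
    Shapiro-Wilk normality gate, Hedges g1 with noncentral-t confidence
    intervals, Cousineau-Morey within-subject standard errors, and
    cross-measure delta regressions). A synthetic eye-trace simulator with
    ground-truth event labels makes every stage testable without human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
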