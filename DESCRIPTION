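Package: tapsync
Title: Finger-Tapping Kinematics and Outcome Statistics for Music-Supported
    Stroke Rehabilitation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing fine motor recovery after stroke from
    force-transducer finger-tapping recordings and standard clinical
    instruments. Provides preprocessing of 3 kHz force traces (edge trimming,
    calibration to Newtons, Bartlett-window smoothing), threshold-based tap
    onset/offset detection with refractory rules, inter-tap-interval speed and
    variability metrics, circular statistics for metronome-paced tapping
    (mean resultant length, Rayleigh test), scoring of the nine-hole pegboard
    test, Profile of Mood States subscales and faces-scale mood ratings,
    covariate-adaptive minimization randomization, and a mixed repeated-
    measures ANOVA with Mauchly sphericity testing, Greenhouse-Geisser
    correction and generalized eta-squared effect sizes, together with the
    nonparametric battery (Fisher exact, Mann-Whitney, Friedman, Welch t)
    used for such cohorts. A synthetic-data module generates force traces
    with known ground-truth taps and two-group cohorts so that every stage
    of the pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
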