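Package: phonolaryn
Title: Multidimensional Voice Pathology Examination Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided examination of dysphonic voices following the
    five-step clinical protocol: subjective questionnaires (Voice Handicap
    Index and its short form), perceptual GRBAS ratings, objective acoustic
    analysis of sustained vowels (fundamental frequency, jitter, shimmer,
    harmonics-to-noise ratio, frequency range), automatic Yanagihara grading
    of narrowband spectrograms, aerodynamic indices (maximum phonation time,
    phonorespiratory index), and pixel-level measures from stroboscopic
    laryngeal images (glottal-space area, lesion sizes, fold deviation angle,
    movement index). Results are combined into a 13-axis vocal profile whose
    polygon area summarises severity, persisted as XML patient sessions, and
    rendered as self-contained HTML reports. Seeded synthetic voice and
    strobe-frame generators with known ground truth make every analysis
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
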