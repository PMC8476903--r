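Package: baods
Title: Beam-Angle Optimization for Double-Scattering Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks gantry angles for three-port double-scattering proton
    plans from CT anatomy alone. A beam's-eye-view ray collector samples
    Hounsfield units and eight structure masks along 25 parallel rays per
    gantry angle; a convolutional network maps the assembled feature array
    to a 360-element beam-angle ranking score; a greedy rule with a minimum
    angular separation picks the three treatment angles; conformity index
    and dose-volume metrics evaluate the resulting plan. Includes a
    synthetic abdominal phantom generator, a minimal DICOM-RT reader and
    writer, and training utilities (L1/L2/smooth-L1 losses, Adam,
    patient-wise K-fold cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
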