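Package: isodvh
Title: Isoeffective DVH Conversion and Radiotherapy Treatment-Gap Compensation
Version: 0.1.0
Authors@R: person("Medical Physics", "Tools", email = "devnull@example.org",
    role = c("aut", "cre"))
Description: Converts physical dose-volume histograms (DVHs) into
    repopulation-corrected BED and EQD2 histograms per structure using the
    linear-quadratic model, including an incomplete-repair factor for
    twice-daily fractionation.  Builds and scores treatment-gap compensation
    schedules under RCR/NCCP constraints, computes DVHs from dose grids and
    contoured structures (including a narrow DICOM RT-Dose/RT-Structure
    reader and writer), validates DVH engines via 1-D gamma analysis, and
    generates synthetic phantoms with analytically known DVHs for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
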