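Package: caflux
Title: Calcium-Handling Analysis of Cardiomyocyte Fluorescence Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of ratiometric calcium-dye recordings from paced
    ventricular myocytes: background subtraction and hyperbolic ratio-to-Ca2+
    calibration with explicit dye-saturation handling, segmentation and
    averaging of electrically evoked calcium transients (CaT) and of the
    caffeine-evoked release (CaffT), buffering-scaled flux decomposition into
    SERCA, NCX, SR backflux and sarcolemmal leak rate constants, derived
    physiological metrics (diastolic/systolic/resting Ca2+, SR load,
    fractional release, CaT90), cell-area shortening from image stacks, and
    animal-nested hierarchical statistics that avoid pseudo-replication.
    Includes a forward simulator of a paced myocyte with an SR compartment,
    rendered into noisy two-channel fluorescence, so that every analysis
    stage is verifiable by parameter recovery against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
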