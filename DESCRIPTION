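Package: phytophys
Title: Phytoplankton Photophysiology: Fluorescence Induction, Quenching,
    Gas Exchange and Diel Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for laboratory photophysiology of microalgae:
    fitting of single-turnover (fast repetition rate) chlorophyll
    fluorescence induction curves with PSII connectivity, PAM quenching
    parameters (Fv/Fm, PhiPSII, qP, NPQ) and 77K/room-temperature emission
    spectra, Clark-electrode oxygen trace analysis with post-illumination
    uptake detection, 14C carbon-fixation rates and Jassby-Platt
    photosynthesis-irradiance curve fitting, derived optical parameters
    (electron transport rate, chlorophyll-specific PSII absorption), growth
    and cell-composition bookkeeping, and diel-cycle hysteresis analysis.
    Includes seeded synthetic-data generators for every input kind, with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    withr,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
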