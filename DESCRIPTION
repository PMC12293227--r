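Package: calmod
Title: Behavioral-State Modulation Analysis of Astrocytic and Neuronal
    Calcium Imaging Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trace-level analysis of simultaneous astrocytic and neuronal
    two-photon calcium imaging recorded during spontaneous behavior on a
    running wheel. Provides deltaF/F extraction (linear detrend, neuropil
    subtraction, percentile baseline on a Savitzky-Golay smoothed trace),
    noise-adaptive calcium event detection with zero-crossing event
    extents, behavioral-state segmentation (Still, Still-Whisking,
    Locomotion) from wheel speed and whisker motion energy, whisking and
    locomotion modulation indices with the segment-inclusion filters used
    in the field, still-to-locomotion transition metrics (activation rate,
    response reliability, event onset lag), and two-level hierarchical
    bootstrap inference for nested mouse/ROI data. A synthetic-session
    generator with known ground truth emulates wild-type-like and
    IP3R2-knockout-like recordings for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
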