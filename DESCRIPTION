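Package: mepmap
Title: Motor-Evoked Potential Mapping and State-Dependent TMS Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcranial magnetic stimulation (TMS)
    motor mapping with surface electromyography (EMG). Provides zero-phase
    band-pass filtering and epoch segmentation of continuous EMG around TMS
    triggers, event-related average motor-evoked potential (MEP)
    quantification (peak-to-peak amplitude, baseline threshold-crossing
    counts, automatic onset latency), amplitude-weighted circular statistics
    for coil-orientation preference, scalp t-statistic maps with
    triangulation-based interpolation and sub-cell contour-area estimation,
    recruitment curves and motor-threshold rules, proximity screening of
    stimulation targets against motor-confound distance cutoffs, electric
    field threshold sweeps, inverse-distance-weighted MEP volumes, and
    effect-size/power utilities. A synthetic-experiment generator emulates
    state-dependent corticospinal excitability (distance decay, orientation
    tuning, movement-dependent thresholds, intensity-dependent latencies) so
    that every analysis stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    grDevices,
    interp,
    jsonlite,
    RNifti,
    signal,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
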