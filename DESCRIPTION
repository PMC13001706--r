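Package: fragmap
Title: Neural Fragility Mapping of Intracranial EEG for Seizure Onset Zone
    Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the neural fragility biomarker for seizure onset
    zone localization from intracranial EEG. Provides an annotated Epoch
    container for multichannel voltage recordings, zero-phase Butterworth
    bandpass and notch preprocessing, sliding-window linear dynamical
    system identification by ridge regression with adaptive regularization
    chosen by bisection, a closed-form minimum two-norm structured
    perturbation analysis that quantifies how easily each electrode's
    dynamics can be pushed to marginal instability, per-window reverse
    scaled normalization, electrode ranking for seizure onset zone
    estimation, a synthetic piecewise-stationary seizure generator with
    planted fragile nodes for validation, heatmap and group comparison
    visualizations, and HDF5/EDF/TSV input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    parallel,
    signal,
    ggplot2,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
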