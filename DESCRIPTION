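Package: retrotrack
Title: Retrospective Quantification of Nuclear-Cytoplasmic Translocation in
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the retrospective analysis of protein
    nuclear-cytoplasmic translocation in single-channel fluorescence
    time-lapse microscopy. Live-cell frames are registered to an end-point
    fixed-cell reference by masked normalized cross-correlation, nuclei and
    cytoplasm are segmented from the fixed nuclear stain and the first
    registered frame, motile or mis-segmented cells are detected by a robust
    regression of per-nucleus intensity standard deviation on mean, and
    per-cell translocation kinetics are quantified by the nuclear-to-
    cytoplasmic ratio, nuclear accumulation, nuclear increment and
    difference-variation descriptors. A ground-truthed synthetic field
    generator emulating stimulated translocation experiments is included for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Software, SingleCell
RoxygenNote: 7.3.3
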