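Package: vsdpop
Title: Population-Response Analysis of Voltage-Sensitive Dye Imaging under
    Optogenetic and Electrical Microstimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mesoscale voltage-sensitive dye imaging
    (VSDI) of stimulus-evoked cortical population responses. Converts raw
    multi-trial fluorescence stacks into trial-averaged delta-f/f movies
    (frame-zero division, blank-trial subtraction, stimulation-artifact frame
    and photobleach pixel masking), extracts peak-ROI time courses with the
    normalization schemes used to compare optogenetic pulse durations and
    intracortical microstimulation, performs concentric-ring space-time
    analysis (space-time maps, summed activation, spatial profiles,
    distance-resolved time courses), maps per-pixel decay time to threshold
    with sub-frame linear interpolation, quantifies opsin-YFP expression area
    with a label-shuffle control, and provides the nonparametric statistics
    used throughout. Includes a synthetic-session generator with ground truth
    emulating the recording conditions so the full pipeline runs and is
    testable without in-vivo data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synth.R'
    'preprocess.R'
    'timecourse.R'
    'rings.R'
    'decay.R'
    'yfp.R'
    'stats.R'
    'io.R'
    'pipeline.R'
    'zzz.R'
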