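#' vsdpop: population-response analysis of voltage-sensitive dye imaging
#'
#' Mesoscale VSDI reports the summed membrane-potential changes of neuronal
#' populations as fractional fluorescence changes (delta-f/f) per pixel.
#' This package turns raw multi-trial fluorescence stacks evoked by
#' optogenetic or electrical (ICMS) stimulation into the standard
#' spatio-temporal summaries of such experiments:
#'
#' * preprocessing: frame-zero division, blank-trial subtraction, trial
#'   averaging, laser-artifact frame and photobleach pixel masking
#'   ([preprocessSession()]);
#' * peak-ROI time courses and normalization schemes
#'   ([extractTimeCourse()], [normalizeTo10ms()], [normalizeToOwnPeak()],
#'   [grandAverage()]);
#' * concentric-ring space-time analysis ([buildRings()], [spaceTimeMap()],
#'   [summedActivation()], [spatialProfile()], [ringTimeCourse()]);
#' * per-pixel decay-time-to-threshold maps ([decayTimeMap()],
#'   [decayDistributions()]);
#' * YFP expression-area quantification ([normalizeYfp()],
#'   [countExpressingPixels()], [groupDifferenceShuffle()]);
#' * nonparametric statistics ([rankSumTest()], [signRankTest()],
#'   [summarizeSample()], [firstLastTrialCheck()]).
#'
#' A synthetic-session generator with ground truth ([simulateSession()],
#' [vsdPreset()]) emulates the recording conditions so the full pipeline
#' ([runPipeline()]) runs without in-vivo data.
#'
#' @keywords internal
"_PACKAGE"
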