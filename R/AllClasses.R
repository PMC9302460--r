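#' @import methods
#' @importFrom stats rnorm runif sd var qt cor quantile qnorm pnorm qlnorm
#'   qnbinom rgamma median aggregate
#' @importFrom utils write.table read.table head
NULL

#' SensorLayout: a planar sensor array with a neighbor relation
#'
#' Holds channel identities, flattened 2-d sensor positions (arbitrary planar
#' units, "flat helmet" view) and the distance threshold that defines the
#' first-order neighbor relation used both by the synthetic planar gradient
#' transform and by the searchlight / cluster adjacency.
#'
#' @slot channelIds character vector of unique channel labels.
#' @slot positions numeric matrix (channels x 2) of planar coordinates.
#' @slot neighborThreshold single positive number; channels closer than this
#'   (strictly) are neighbors.
#' @seealso [makeGridLayout()], [neighborMatrix()]
#' @export
setClass("SensorLayout",
  representation(
    channelIds = "character",
    positions = "matrix",
    neighborThreshold = "numeric"
  )
)

setValidity("SensorLayout", function(object) {
  msg <- character()
  n <- length(object@channelIds)
  if (anyDuplicated(object@channelIds))
    msg <- c(msg, "channel ids must be unique")
  if (!is.numeric(object@positions) || ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be a numeric matrix with 2 columns")
  if (nrow(object@positions) != n)
    msg <- c(msg, "positions must have one row per channel")
  if (!all(is.finite(object@positions)))
    msg <- c(msg, "positions must be finite")
  if (length(object@neighborThreshold) != 1L ||
      !is.finite(object@neighborThreshold) || object@neighborThreshold <= 0)
    msg <- c(msg, "neighborThreshold must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' EffectSpec: a known class effect injected into simulated epochs
#'
#' Describes one ground-truth effect: which trial label variable drives it,
#' which channels and time window carry it, and the per-class signal offset.
#' The simulator adds \code{amplitude[class] * envelope(t)} to the named
#' channels inside the window; recovery tests compare detected clusters
#' against these fields.
#'
#' @slot variable name of the trial label column this effect encodes.
#' @slot channels character vector, subset of the layout's channel ids.
#' @slot windowMs numeric length-2, effect window (ms relative to stimulus
#'   onset), must lie inside the epoch.
#' @slot amplitudes named numeric vector, one signal offset per class level;
#'   at least two distinct values (otherwise nothing is decodable).
#' @slot waveform envelope identifier: \code{"halfcosine"} (flat top with
#'   10 ms half-cosine ramps — a sustained field offset) or \code{"burst"}
#'   (the same envelope times a 10 Hz carrier — an oscillatory evoked
#'   transient with essentially no sub-band energy, which passes a
#'   1-30 Hz zero-phase bandpass without smearing outside its window).
#' @seealso [effectSpec()], [simulateEpochs()]
#' @export
setClass("EffectSpec",
  representation(
    variable = "character",
    channels = "character",
    windowMs = "numeric",
    amplitudes = "numeric",
    waveform = "character"
  )
)

setValidity("EffectSpec", function(object) {
  msg <- character()
  if (length(object@variable) != 1L) msg <- c(msg, "variable must be a single name")
  if (length(object@channels) < 1L) msg <- c(msg, "at least one channel required")
  if (length(object@windowMs) != 2L || object@windowMs[1] >= object@windowMs[2])
    msg <- c(msg, "windowMs must be [start, end] with start < end")
  if (is.null(names(object@amplitudes)) || any(names(object@amplitudes) == ""))
    msg <- c(msg, "amplitudes must be named by class level")
  if (length(unique(object@amplitudes)) < 2L)
    msg <- c(msg, "amplitudes must contain at least 2 distinct values")
  if (!object@waveform %in% c("halfcosine", "burst"))
    msg <- c(msg, "unknown waveform")
  if (length(msg)) msg else TRUE
})

#' EpochSet: epoched multichannel time series with trial metadata
#'
#' The central container: a trials x channels x samples numeric array with
#' its sampling rate, the time of the first sample relative to stimulus
#' onset, a per-trial metadata table, and a logical missing-sample mask of
#' the same shape. Masked cells are stored as \code{NA} in \code{data} and
#' are excluded from every downstream computation.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot t0Ms time of the first sample in ms relative to stimulus onset.
#' @slot trials data.frame with one row per trial (subject, item,
#'   repetition, class labels, `valid` flag, ...).
#' @slot missingMask logical array, same shape as `data`.
#' @slot channelIds character vector naming the channel dimension.
#' @slot metadata free-form list (simulation ground truth, provenance).
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    fs = "numeric",
    t0Ms = "numeric",
    trials = "data.frame",
    missingMask = "array",
    channelIds = "character",
    metadata = "list"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array (trials x channels x samples)")
  if (!identical(dim(object@missingMask), d))
    msg <- c(msg, "missingMask must have the same shape as data")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(d) == 3L) {
    if (nrow(object@trials) != d[1])
      msg <- c(msg, "trials must have one row per trial")
    if (length(object@channelIds) != d[2])
      msg <- c(msg, "channelIds must match the channel dimension")
  }
  if (length(msg)) msg else TRUE
})

#' PlanarEpochSet: horizontal/vertical planar gradient components
#'
#' Output of [planarGradient()]: per channel and sample the two tangential
#' derivative estimates of the field. Combine with [combinePlanar()] to get
#' the non-negative gradient magnitude used for decoding.
#'
#' @slot h,v numeric arrays, trials x channels x samples (components).
#' @slot fs,t0Ms,trials,missingMask,channelIds,metadata as in [EpochSet-class].
#' @export
setClass("PlanarEpochSet",
  representation(
    h = "array",
    v = "array",
    fs = "numeric",
    t0Ms = "numeric",
    trials = "data.frame",
    missingMask = "array",
    channelIds = "character",
    metadata = "list"
  )
)

setValidity("PlanarEpochSet", function(object) {
  msg <- character()
  if (!identical(dim(object@h), dim(object@v)))
    msg <- c(msg, "h and v must have identical shapes")
  if (!identical(dim(object@h), dim(object@missingMask)))
    msg <- c(msg, "missingMask must match component shape")
  if (length(msg)) msg else TRUE
})

#' SearchlightSpec: geometry of the spatiotemporal searchlight
#'
#' A searchlight at a (channel, time) center collects the center's
#' first-order neighbors (optionally plus the center itself) and a time
#' window of fixed duration. At 300 Hz a 150 ms window is 45 samples, so a
#' 10-channel searchlight yields 450 features and a 4-channel one 180.
#'
#' @slot windowMs window duration in ms (default 150).
#' @slot alignment one of "centered", "trailing", "leading".
#' @slot includeCenter include the center channel in the channel set.
#' @seealso [searchlightSpec()], [windowSamples()], [searchlightFeatures()]
#' @export
setClass("SearchlightSpec",
  representation(
    windowMs = "numeric",
    alignment = "character",
    includeCenter = "logical"
  )
)

setValidity("SearchlightSpec", function(object) {
  msg <- character()
  if (length(object@windowMs) != 1L || object@windowMs <= 0)
    msg <- c(msg, "windowMs must be a single positive duration")
  if (!object@alignment %in% c("centered", "trailing", "leading"))
    msg <- c(msg, "alignment must be centered, trailing or leading")
  if (length(msg)) msg else TRUE
})

#' CvScheme: repeated stratified cross-validation with undersampling
#'
#' Five-fold stratified cross-validation repeated five times with fresh fold
#' assignments, class-balanced by random undersampling before each repeat's
#' fold split (so both training and validation folds are balanced).
#'
#' @slot nFolds number of folds (default 5).
#' @slot nRepeats number of repeats with fresh fold assignment (default 5).
#' @slot undersample balance classes by random undersampling per repeat.
#' @slot seed integer seed from which per-repeat streams are derived.
#' @seealso [cvScheme()], [crossValidate()]
#' @export
setClass("CvScheme",
  representation(
    nFolds = "numeric",
    nRepeats = "numeric",
    undersample = "logical",
    seed = "numeric"
  )
)

setValidity("CvScheme", function(object) {
  msg <- character()
  if (object@nFolds < 2) msg <- c(msg, "nFolds must be >= 2")
  if (object@nRepeats < 1) msg <- c(msg, "nRepeats must be >= 1")
  if (length(msg)) msg else TRUE
})

#' AccuracyMap: channels x time decoding accuracy for one subject
#'
#' @slot accuracy numeric matrix channels x time; NA where undefined.
#' @slot nTrials integer matrix of trials actually used per cell.
#' @slot timesMs numeric vector of evaluated time points (ms).
#' @slot channelIds character vector naming the rows.
#' @slot variable decoded label variable name.
#' @slot subject subject identifier.
#' @export
setClass("AccuracyMap",
  representation(
    accuracy = "matrix",
    nTrials = "matrix",
    timesMs = "numeric",
    channelIds = "character",
    variable = "character",
    subject = "character"
  )
)

setValidity("AccuracyMap", function(object) {
  msg <- character()
  if (!identical(dim(object@accuracy), dim(object@nTrials)))
    msg <- c(msg, "accuracy and nTrials must have identical shapes")
  if (nrow(object@accuracy) != length(object@channelIds))
    msg <- c(msg, "one row per channel required")
  if (ncol(object@accuracy) != length(object@timesMs))
    msg <- c(msg, "one column per time point required")
  a <- object@accuracy[!is.na(object@accuracy)]
  if (length(a) && (min(a) < 0 || max(a) > 1))
    msg <- c(msg, "defined accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' StratifiedNull: empirical null of decoding accuracy per cell
#'
#' Mean and SD of decoding accuracy over label randomizations constrained to
#' the given strata (e.g. shuffling word-length labels within each object
#' category). Cells with zero SD are flagged: their Z score is undefined.
#'
#' @slot nullMean,nullSd numeric matrices channels x time.
#' @slot nRand number of randomizations (default 100).
#' @slot strata description of the strata used for the constrained shuffle.
#' @slot timesMs,channelIds,variable as in [AccuracyMap-class].
#' @export
setClass("StratifiedNull",
  representation(
    nullMean = "matrix",
    nullSd = "matrix",
    nRand = "numeric",
    strata = "character",
    timesMs = "numeric",
    channelIds = "character",
    variable = "character"
  )
)

setValidity("StratifiedNull", function(object) {
  msg <- character()
  if (!identical(dim(object@nullMean), dim(object@nullSd)))
    msg <- c(msg, "nullMean and nullSd must have identical shapes")
  s <- object@nullSd[!is.na(object@nullSd)]
  if (length(s) && min(s) < 0) msg <- c(msg, "null SDs must be non-negative")
  if (object@nRand < 2) msg <- c(msg, "nRand must be >= 2")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: group-level cluster-based permutation test output
#'
#' Maximal spatiotemporally contiguous sets of cells whose one-sample group
#' T statistic exceeds the cluster-forming threshold, each with its cluster
#' mass (sum of T) and a permutation p-value from the max-mass null under
#' whole-subject sign flips.
#'
#' @slot cells data.frame: cluster, channel, timeMs, T (one row per member cell).
#' @slot clusters data.frame: cluster, mass, p (sorted by decreasing mass).
#' @slot threshold cluster-forming T threshold used.
#' @slot nPerm number of sign-flip permutations.
#' @slot nSubjects number of subject maps.
#' @slot alphaCluster cell-level one-sided alpha defining the threshold.
#' @export
setClass("ClusterResult",
  representation(
    cells = "data.frame",
    clusters = "data.frame",
    threshold = "numeric",
    nPerm = "numeric",
    nSubjects = "numeric",
    alphaCluster = "numeric"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (nrow(object@clusters)) {
    p <- object@clusters$p
    if (any(p <= 0 | p > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
    m <- object@clusters$mass
    if (is.unsorted(rev(m))) msg <- c(msg, "clusters must be sorted by decreasing mass")
    if (any(diff(p[order(-m)]) < -1e-12))
      msg <- c(msg, "p must be non-increasing in mass")
  }
  if (length(msg)) msg else TRUE
})

#' PipelineConfig: a fully serializable pipeline configuration
#'
#' Bundles the generator, preprocessing, searchlight, decoding and inference
#' parameters plus a single root seed; re-running an identical config
#' reproduces all outputs bit-identically.
#'
#' @slot generator,preprocessing,searchlight,decoding,inference named lists
#'   of stage parameters (see [pipelineConfig()] for fields and defaults).
#' @slot outputDir optional directory for TSV outputs ("" = don't write).
#' @slot seed root integer seed; all stage RNG streams derive from it.
#' @export
setClass("PipelineConfig",
  representation(
    generator = "list",
    preprocessing = "list",
    searchlight = "list",
    decoding = "list",
    inference = "list",
    outputDir = "character",
    seed = "numeric"
  )
)
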