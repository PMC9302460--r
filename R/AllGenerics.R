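#' Accessor generics
#'
#' Small accessor family for the package's containers; slot access from user
#' code is discouraged.
#'
#' @param object a package object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelIds", function(object, ...) standardGeneric("channelIds"))

#' @rdname accessors
#' @export
setGeneric("sensorPositions", function(object, ...) standardGeneric("sensorPositions"))

#' @rdname accessors
#' @export
setGeneric("neighborThreshold", function(object, ...) standardGeneric("neighborThreshold"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(object, ...) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object, ...) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("timesMs", function(object, ...) standardGeneric("timesMs"))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(object, ...) standardGeneric("trialInfo"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(object, ...) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object, ...) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object, ...) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object, ...) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("accuracyValues", function(object, ...) standardGeneric("accuracyValues"))

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(object, ...) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setGeneric("clusterCells", function(object, ...) standardGeneric("clusterCells"))

## ---- SensorLayout ----

#' @rdname accessors
#' @export
setMethod("channelIds", "SensorLayout", function(object, ...) object@channelIds)

#' @rdname accessors
#' @export
setMethod("sensorPositions", "SensorLayout", function(object, ...) {
  p <- object@positions
  rownames(p) <- object@channelIds
  p
})

#' @rdname accessors
#' @export
setMethod("neighborThreshold", "SensorLayout", function(object, ...) object@neighborThreshold)

#' @rdname accessors
#' @export
setMethod("nChannels", "SensorLayout", function(object, ...) length(object@channelIds))

setMethod("show", "SensorLayout", function(object) {
  deg <- degreeStats(object)
  cat("SensorLayout with", length(object@channelIds), "channels\n")
  cat("  neighbor threshold:", format(object@neighborThreshold), "\n")
  cat(sprintf("  neighbors/channel: mean %.1f (SD %.1f, range %d-%d)\n",
              deg["mean"], deg["sd"], as.integer(deg["min"]), as.integer(deg["max"])))
})

## ---- EpochSet ----

#' @rdname accessors
#' @export
setMethod("channelIds", "EpochSet", function(object, ...) object@channelIds)

#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(object, ...) object@data)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object, ...) object@fs)

#' @rdname accessors
#' @export
setMethod("timesMs", "EpochSet", function(object, ...) {
  object@t0Ms + (seq_len(dim(object@data)[3]) - 1L) * 1000 / object@fs
})

#' @rdname accessors
#' @export
setMethod("trialInfo", "EpochSet", function(object, ...) object@trials)

#' @rdname accessors
#' @export
setMethod("missingMask", "EpochSet", function(object, ...) object@missingMask)

#' @rdname accessors
#' @export
setMethod("nTrials", "EpochSet", function(object, ...) dim(object@data)[1])

#' @rdname accessors
#' @export
setMethod("nChannels", "EpochSet", function(object, ...) dim(object@data)[2])

#' @rdname accessors
#' @export
setMethod("nSamples", "EpochSet", function(object, ...) dim(object@data)[3])

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  tms <- timesMs(object)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  time: %.1f to %.1f ms; %d valid trials; %.2f%% samples masked\n",
              tms[1], tms[length(tms)],
              sum(object@trials$valid %||% rep(TRUE, d[1])),
              100 * mean(object@missingMask)))
})

## ---- PlanarEpochSet ----

#' @rdname accessors
#' @export
setMethod("channelIds", "PlanarEpochSet", function(object, ...) object@channelIds)

#' @rdname accessors
#' @export
setMethod("trialInfo", "PlanarEpochSet", function(object, ...) object@trials)

#' @rdname accessors
#' @export
setMethod("samplingRate", "PlanarEpochSet", function(object, ...) object@fs)

setMethod("show", "PlanarEpochSet", function(object) {
  d <- dim(object@h)
  cat(sprintf("PlanarEpochSet: %d trials x %d channels x %d samples @ %g Hz (h/v components)\n",
              d[1], d[2], d[3], object@fs))
})

## ---- AccuracyMap ----

#' @rdname accessors
#' @export
setMethod("accuracyValues", "AccuracyMap", function(object, ...) {
  a <- object@accuracy
  dimnames(a) <- list(object@channelIds, format(object@timesMs))
  a
})

#' @rdname accessors
#' @export
setMethod("channelIds", "AccuracyMap", function(object, ...) object@channelIds)

#' @rdname accessors
#' @export
setMethod("timesMs", "AccuracyMap", function(object, ...) object@timesMs)

setMethod("show", "AccuracyMap", function(object) {
  a <- object@accuracy
  cat(sprintf("AccuracyMap '%s' (subject %s): %d channels x %d time points\n",
              object@variable, object@subject, nrow(a), ncol(a)))
  if (any(!is.na(a)))
    cat(sprintf("  accuracy: mean %.3f, max %.3f; %d undefined cells\n",
                mean(a, na.rm = TRUE), max(a, na.rm = TRUE), sum(is.na(a))))
})

## ---- StratifiedNull ----

setMethod("show", "StratifiedNull", function(object) {
  cat(sprintf("StratifiedNull '%s': %d randomizations, strata: %s\n",
              object@variable, object@nRand,
              if (nchar(object@strata)) object@strata else "(none)"))
  cat(sprintf("  null mean over cells: %.3f\n", mean(object@nullMean, na.rm = TRUE)))
})

## ---- ClusterResult ----

#' @rdname accessors
#' @export
setMethod("clusterTable", "ClusterResult", function(object, ...) object@clusters)

#' @rdname accessors
#' @export
setMethod("clusterCells", "ClusterResult", function(object, ...) object@cells)

setMethod("show", "ClusterResult", function(object) {
  k <- nrow(object@clusters)
  cat(sprintf("ClusterResult: %d cluster%s (threshold T > %.3f, %d permutations, %d subjects)\n",
              k, if (k == 1) "" else "s", object@threshold,
              object@nPerm, object@nSubjects))
  if (k) {
    sig <- object@clusters$p < 0.05
    cat(sprintf("  %d with p < 0.05; top: mass %.1f, p = %.4f\n",
                sum(sig), object@clusters$mass[1], object@clusters$p[1]))
  } else {
    cat("  no significant clusters\n")
  }
})
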