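#' Construct a SearchlightSpec
#'
#' @param windowMs searchlight window duration in ms (default 150).
#' @param alignment window placement relative to the evaluated time point:
#'   `"centered"` (default, symmetric), `"trailing"` (window ends at the
#'   center) or `"leading"` (window starts at the center).
#' @param includeCenter include the center channel in the searchlight
#'   channel set (default `TRUE`; with it, a channel with 9 neighbors gives
#'   a 10-channel searchlight and, at 45 window samples, 450 features).
#' @return a [SearchlightSpec-class].
#' @export
searchlightSpec <- function(windowMs = 150, alignment = "centered",
                            includeCenter = TRUE) {
  new("SearchlightSpec", windowMs = windowMs, alignment = alignment,
      includeCenter = includeCenter)
}

#' Searchlight window length in samples
#'
#' `round(windowMs * fs / 1000)`: 45 samples for a 150 ms window at 300 Hz.
#'
#' @param spec a [SearchlightSpec-class] (or a window duration in ms).
#' @param fs sampling rate in Hz.
#' @return integer sample count.
#' @export
windowSamples <- function(spec, fs) {
  w <- if (is(spec, "SearchlightSpec")) spec@windowMs else spec
  as.integer(round(w * fs / 1000))
}

## Sample indices of the window at a center index, or NULL when the window
## would extend beyond 1..nS (the center is then undefined, not truncated).
windowIndicesAt <- function(center, nWin, nS, alignment) {
  start <- switch(alignment,
    centered = center - (nWin - 1L) %/% 2L,
    trailing = center - nWin + 1L,
    leading  = center)
  idx <- start:(start + nWin - 1L)
  if (idx[1] < 1L || idx[nWin] > nS) NULL else idx
}

#' Extract the per-trial feature matrix of one searchlight
#'
#' Collects, for the searchlight centered at `(centerChannel,
#' centerTimeIndex)`, the center's first-order neighbors (plus the center
#' itself when `includeCenter`) over the spec's time window, and flattens
#' them channel-major (channel 1 samples 1..w, channel 2 samples 1..w, ...)
#' into a trials x features matrix. Trials with any missing cell inside the
#' searchlight are dropped and reported via `keptTrials`.
#'
#' @param epochs an [EpochSet-class].
#' @param centerChannel channel id or index of the center.
#' @param centerTimeIndex sample index of the evaluated time point.
#' @param layout the [SensorLayout-class] providing the neighbor relation.
#' @param spec a [SearchlightSpec-class].
#' @return `NULL` when the window does not fit inside the epoch (the center
#'   is undefined); otherwise a list with `X` (kept trials x features),
#'   `keptTrials` (row indices into the epoch's trials), `channels`
#'   (channel indices, sorted) and `sampleIndices`.
#' @export
searchlightFeatures <- function(epochs, centerChannel, centerTimeIndex,
                                layout, spec = searchlightSpec()) {
  if (is.character(centerChannel)) {
    centerChannel <- match(centerChannel, channelIds(epochs))
    if (is.na(centerChannel)) abort("unknown center channel")
  }
  nS <- dim(epochs@data)[3]
  nWin <- windowSamples(spec, epochs@fs)
  winIdx <- windowIndicesAt(as.integer(centerTimeIndex), nWin, nS, spec@alignment)
  if (is.null(winIdx)) return(NULL)
  adj <- neighborMatrix(layout)
  chs <- which(adj[centerChannel, ])
  if (spec@includeCenter) chs <- sort(c(centerChannel, chs))
  if (!length(chs)) abort("searchlight has an empty channel set")
  slab <- epochs@data[, chs, winIdx, drop = FALSE]
  ## channel-major flatten: sample fastest within channel
  X <- matrix(aperm(slab, c(1, 3, 2)), dim(slab)[1], nWin * length(chs))
  keep <- which(rowSums(is.na(X)) == 0L)
  list(X = X[keep, , drop = FALSE], keptTrials = keep,
       channels = chs, sampleIndices = winIdx)
}
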