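#' Zero-phase bandpass filter and downsample an EpochSet
#'
#' Applies a 4th-order Butterworth bandpass (defaults 1-30 Hz) forwards and
#' backwards (`signal::filtfilt`, zero phase, attenuation doubled), then
#' decimates to `targetFs`, which must divide `fs` exactly (e.g. 1200 Hz
#' acquisition to 300 Hz by keeping every 4th sample). The missing mask is
#' propagated conservatively: a downsampled cell is missing when any source
#' sample in its decimation block was missing. Missing samples are zeroed
#' before filtering so contamination is confined to the mask.
#'
#' @param epochs an [EpochSet-class].
#' @param low,high band edges in Hz, `0 < low < high < fs / 2`.
#' @param targetFs output sampling rate; must divide `fs`, and `high` must
#'   stay below its Nyquist frequency.
#' @param order Butterworth order per pass (default 4).
#' @return a filtered, decimated [EpochSet-class].
#' @export
bandpassDownsample <- function(epochs, low = 1, high = 30,
                               targetFs = samplingRate(epochs), order = 4) {
  fs <- samplingRate(epochs)
  if (!(low > 0 && low < high && high < fs / 2))
    abort("need 0 < low < high < fs/2")
  if (high >= targetFs / 2)
    abort("high band edge must be below the Nyquist frequency of targetFs")
  k <- fs / targetFs
  if (abs(k - round(k)) > 1e-9)
    abort("targetFs must divide fs exactly (decimation)")
  k <- as.integer(round(k))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  d <- dim(epochs@data)
  nTr <- d[1]; nCh <- d[2]; nS <- d[3]
  mask <- epochs@missingMask
  x <- epochs@data
  x[mask] <- 0
  filt <- array(0, dim = d)
  for (tr in seq_len(nTr)) {
    for (ch in seq_len(nCh)) {
      filt[tr, ch, ] <- signal::filtfilt(bf, x[tr, ch, ])
    }
  }
  keep <- seq(1L, nS, by = k)
  newS <- length(keep)
  newData <- filt[, , keep, drop = FALSE]
  ## block-wise any-missing propagation: block j covers source samples
  ## (j-1)*k+1 ... min(j*k, nS)
  newMask <- array(FALSE, dim = c(nTr, nCh, newS))
  for (j in seq_len(newS)) {
    idx <- ((j - 1L) * k + 1L):min(j * k, nS)
    newMask[, , j] <- apply(mask[, , idx, drop = FALSE], c(1, 2), any)
  }
  newData[newMask] <- NA_real_
  epochSet(newData, fs = targetFs, t0Ms = epochs@t0Ms, trials = epochs@trials,
           channelIds = epochs@channelIds, missingMask = newMask,
           metadata = c(epochs@metadata,
                        list(bandpass = c(low = low, high = high),
                             sourceFs = fs)))
}

## Per-channel planar estimation operators. For channel i with first-order
## neighbors j, the tangential gradient g = (gx, gy) is the weighted
## least-squares solution of (F_j - F_i) ~ g . (p_j - p_i), with inverse
## squared-distance weights. Exact for fields linear in position; linear in
## the input field. Returns nCh x nCh matrices Wh, Wv (rows = output
## channels) and a logical vector of channels with no neighbors.
planarOperators <- function(layout) {
  adj <- neighborMatrix(layout)
  pos <- layout@positions
  nCh <- nrow(pos)
  Wh <- matrix(0, nCh, nCh)
  Wv <- matrix(0, nCh, nCh)
  isolated <- logical(nCh)
  for (i in seq_len(nCh)) {
    nb <- which(adj[i, ])
    if (!length(nb)) { isolated[i] <- TRUE; next }
    D <- sweep(pos[nb, , drop = FALSE], 2, pos[i, ])
    w <- 1 / rowSums(D^2)
    A <- crossprod(D, D * w)           # 2 x 2
    ## pseudoinverse via eigen: collinear neighbor sets (rank 1) get the
    ## gradient component along the available direction only
    e <- eigen(A, symmetric = TRUE)
    pos_ev <- e$values > max(e$values) * 1e-10
    Ainv <- e$vectors[, pos_ev, drop = FALSE] %*%
      (t(e$vectors[, pos_ev, drop = FALSE]) / e$values[pos_ev])
    G <- Ainv %*% t(D * w)             # 2 x m, coefficients on (F_j - F_i)
    Wh[i, nb] <- G[1, ]
    Wh[i, i] <- -sum(G[1, ])
    Wv[i, nb] <- G[2, ]
    Wv[i, i] <- -sum(G[2, ])
  }
  list(Wh = Wh, Wv = Wv, isolated = isolated)
}

#' Synthetic planar gradient transform
#'
#' Estimates, for every channel and sample, the horizontal and vertical
#' tangential derivatives of the recorded field from the differences
#' between the channel and its first-order neighbors (distance-weighted
#' least squares on the neighbor offsets). The transform is linear in the
#' input field and exact for spatially linear fields; a spatially uniform
#' field yields zero components everywhere. Axial gradiometer topographies
#' are bipolar around a source; the combined planar magnitude
#' ([combinePlanar()]) instead peaks above the source, which eases
#' interpretation of sensor-level maps.
#'
#' A channel's components are missing at a sample whenever the channel or
#' any of its neighbors is missing there. Channels with no neighbors are
#' flagged and their components are missing everywhere.
#'
#' @param epochs an [EpochSet-class].
#' @param layout the [SensorLayout-class]; every channel should have at
#'   least one neighbor.
#' @return a [PlanarEpochSet-class].
#' @export
planarGradient <- function(epochs, layout) {
  if (!identical(channelIds(epochs), channelIds(layout)))
    abort("epochs and layout must have identical channel sets")
  ops <- planarOperators(layout)
  if (any(ops$isolated))
    warning(sum(ops$isolated), " isolated channel(s); their planar components are missing")
  d <- dim(epochs@data)
  x <- epochs@data
  x[epochs@missingMask] <- 0          # contamination tracked via mask
  ## channels x (trials * samples) view for one GEMM per component
  m <- matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3])
  h <- aperm(array(ops$Wh %*% m, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  v <- aperm(array(ops$Wv %*% m, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  ## mask: self-or-neighbor missing
  adjSelf <- neighborMatrix(layout) | diag(TRUE, d[2])
  mm <- matrix(aperm(epochs@missingMask, c(2, 1, 3)), d[2], d[1] * d[3])
  pm <- aperm(array((adjSelf %*% mm) > 0, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  if (any(ops$isolated)) pm[, ops$isolated, ] <- TRUE
  h[pm] <- NA_real_
  v[pm] <- NA_real_
  new("PlanarEpochSet", h = h, v = v, fs = epochs@fs, t0Ms = epochs@t0Ms,
      trials = epochs@trials, missingMask = pm,
      channelIds = epochs@channelIds,
      metadata = c(epochs@metadata, list(planar = "wls-neighbor-difference")))
}

#' Combine planar gradient components
#'
#' Per sample, the combined value is the Euclidean norm
#' `sqrt(h^2 + v^2)` of the two tangential components: non-negative,
#' invariant to a joint rotation of (h, v), and maximal above the source.
#' A combined cell is missing when either component is missing.
#'
#' @param planar a [PlanarEpochSet-class].
#' @return an [EpochSet-class] of combined planar gradient magnitudes.
#' @export
combinePlanar <- function(planar) {
  stopifnot(is(planar, "PlanarEpochSet"))
  comb <- sqrt(planar@h^2 + planar@v^2)
  comb[planar@missingMask] <- NA_real_
  epochSet(comb, fs = planar@fs, t0Ms = planar@t0Ms, trials = planar@trials,
           channelIds = planar@channelIds, missingMask = planar@missingMask,
           metadata = c(planar@metadata, list(combined = "euclidean-norm")))
}

#' Keep only valid trials
#'
#' Drops trials whose `valid` flag is `FALSE` (naming errors, disfluencies)
#' and re-indexes the trial metadata consistently.
#'
#' @param epochs an [EpochSet-class] whose trial table has a `valid` column.
#' @return an [EpochSet-class] with only valid trials.
#' @export
selectValidTrials <- function(epochs) {
  valid <- epochs@trials$valid
  if (is.null(valid)) abort("trial metadata has no 'valid' column")
  if (!any(valid)) abort("no valid trials remain")
  if (all(valid)) return(epochs)
  keep <- which(valid)
  trials <- epochs@trials[keep, , drop = FALSE]
  rownames(trials) <- NULL
  epochSet(epochs@data[keep, , , drop = FALSE], fs = epochs@fs,
           t0Ms = epochs@t0Ms, trials = trials,
           channelIds = epochs@channelIds,
           missingMask = epochs@missingMask[keep, , , drop = FALSE],
           metadata = epochs@metadata)
}
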