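#' Fit a Gaussian naive Bayes classifier
#'
#' Per class: prior probability (class frequency), per-feature mean and
#' maximum-likelihood variance (divisor n). Variances are floored at
#' `eps = varFloorFactor * mean(class-feature variances)` (absolute
#' fallback 1e-12 when all features are constant) to avoid degenerate
#' densities on constant features.
#'
#' @param X trials x features numeric matrix.
#' @param y class labels (coerced to factor; its level order is the
#'   canonical class order used for tie-breaking).
#' @param varFloorFactor relative variance floor (default 1e-9).
#' @return an object of class `GnbModel` (list with `classes`, `priors`,
#'   `means`, `vars` — each K x features — and `eps`).
#' @export
fitGnb <- function(X, y, varFloorFactor = 1e-9) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) abort("need at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 2)) abort("every class needs at least 2 trials (variance undefined)")
  K <- nlevels(y); p <- ncol(X)
  means <- matrix(0, K, p, dimnames = list(levels(y), colnames(X)))
  vars <- means
  for (k in seq_len(K)) {
    Xk <- X[y == levels(y)[k], , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    vars[k, ] <- colMeans(Xk^2) - means[k, ]^2
  }
  vars[vars < 0] <- 0
  eps <- varFloorFactor * mean(vars)
  if (eps <= 0) eps <- 1e-12
  vars[vars < eps] <- eps
  structure(list(classes = levels(y), priors = as.numeric(cnt) / length(y),
                 means = means, vars = vars, eps = eps),
            class = "GnbModel")
}

#' Predict with a Gaussian naive Bayes model
#'
#' Class scores are `log prior + sum of log univariate normal densities`
#' (conditional feature independence); `type = "class"` returns the argmax
#' with ties broken toward the first class in the model's canonical class
#' order, `type = "posterior"` the row-normalized posterior probabilities.
#'
#' @param model a `GnbModel` from [fitGnb()].
#' @param X trials x features matrix with the model's feature dimension.
#' @param type `"class"` (default) or `"posterior"`.
#' @return factor of predicted labels, or a trials x classes posterior
#'   matrix.
#' @export
predictGnb <- function(model, X, type = c("class", "posterior")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$means))
    abort("feature dimension mismatch: model has ", ncol(model$means),
          ", data has ", ncol(X))
  K <- length(model$classes)
  W <- t(1 / model$vars)                           # p x K
  MW <- t(model$means / model$vars)                # p x K
  base <- log(model$priors) -
    0.5 * rowSums(log(model$vars)) -
    0.5 * rowSums(model$means^2 / model$vars) -
    0.5 * ncol(X) * log(2 * pi)
  LL <- sweep(-0.5 * (X^2 %*% W) + X %*% MW, 2, base, "+")
  if (type == "posterior") {
    mx <- apply(LL, 1, max)
    P <- exp(LL - mx)
    P <- P / rowSums(P)
    colnames(P) <- model$classes
    return(P)
  }
  factor(model$classes[max.col(LL, ties.method = "first")],
         levels = model$classes)
}

#' Random undersampling to equal class counts
#'
#' Discards randomly selected trials from majority classes until every
#' class is represented by the minority-class count. Deterministic given
#' the seed.
#'
#' @param y class labels.
#' @param seed integer seed.
#' @return sorted integer vector of kept indices.
#' @export
undersample <- function(y, seed = 1) {
  y <- factor(y)
  if (any(table(y) < 1)) abort("every class needs at least 1 trial")
  m <- min(table(y))
  withSeed(deriveSeed(seed, 31), {
    kept <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }))
    sort(kept)
  })
}

#' Construct a CvScheme
#'
#' @param nFolds folds per repeat (default 5).
#' @param nRepeats repeats with fresh random fold assignment (default 5).
#' @param undersample balance classes by random undersampling once per
#'   repeat, before the fold split, so both training and validation folds
#'   are balanced (default `TRUE`).
#' @param seed integer seed; per-repeat streams derive from it.
#' @return a [CvScheme-class].
#' @export
cvScheme <- function(nFolds = 5, nRepeats = 5, undersample = TRUE, seed = 1) {
  new("CvScheme", nFolds = nFolds, nRepeats = nRepeats,
      undersample = undersample, seed = seed)
}

## Build per-repeat CV plans (undersampled kept rows + stratified fold ids)
## for one labeling. Plans are generated in trial-id-sorted space so the
## result is invariant to the physical row order of the data, then mapped
## back to row indices. Returns list of repeats, each list(idx = 0-based
## kept rows, fold = 1..nFolds aligned with idx), or NULL when a class is
## too small for stratified folds after undersampling.
makeCvPlans <- function(y, scheme, trialIds = seq_along(y)) {
  y <- factor(y)
  ord <- order(trialIds)
  yOrd <- y[ord]
  m <- min(table(yOrd))
  if (m < scheme@nFolds) return(NULL)
  lapply(seq_len(scheme@nRepeats), function(r) {
    withSeed(deriveSeed(scheme@seed, 53, r), {
      keptPos <- unlist(lapply(levels(yOrd), function(lv) {
        idx <- which(yOrd == lv)
        if (scheme@undersample && length(idx) > m) sort(sample(idx, m)) else idx
      }))
      keptPos <- sort(keptPos)
      fold <- integer(length(keptPos))
      for (lv in levels(yOrd)) {
        pos <- which(yOrd[keptPos] == lv)
        fold[pos[sample.int(length(pos))]] <-
          rep_len(seq_len(scheme@nFolds), length(pos))
      }
      list(idx = as.integer(ord[keptPos] - 1L), fold = as.integer(fold))
    })
  })
}

#' Repeated stratified cross-validated decoding accuracy
#'
#' Mean classification accuracy of a Gaussian naive Bayes classifier over
#' `nFolds` stratified folds and `nRepeats` repeats with fresh fold
#' assignments, with random undersampling to equal class counts applied
#' once per repeat before the fold split. The result depends on the trials
#' only through `(X, y, trialIds)`: physically reordering rows (with their
#' ids) leaves the accuracy unchanged.
#'
#' @param X trials x features matrix.
#' @param y class labels.
#' @param scheme a [CvScheme-class].
#' @param trialIds stable per-trial identifiers (default row order).
#' @param strict when `TRUE` (default) an infeasible class count (fewer
#'   than `nFolds` trials in the smallest class after undersampling) is an
#'   error; when `FALSE` it yields `NA` (used per searchlight cell).
#' @return mean accuracy in `[0, 1]`, or `NA` when undefined.
#' @export
crossValidate <- function(X, y, scheme = cvScheme(), trialIds = seq_along(y),
                          strict = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) abort("need at least 2 classes")
  plans <- makeCvPlans(y, scheme, trialIds)
  if (is.null(plans)) {
    if (strict) abort("smallest class has fewer than nFolds trials after undersampling")
    return(NA_real_)
  }
  acc <- .gnbCvMany(t(X), matrix(as.integer(y), ncol = 1), list(plans), nlevels(y))
  if (is.nan(acc[1])) NA_real_ else acc[1]
}

## ---- searchlight decoding engine ----

## Shared engine behind decodeMap / buildNull / decodeWithNull. Computes,
## per (channel, time) cell, the observed accuracy and/or the accuracy for
## nRand constrained label randomizations, reusing the cell's feature
## matrix across all labelings (one C++ call per cell). Undersampling and
## fold assignment are re-randomized inside the compiled engine from a
## seed derived per (scheme seed, channel, time, labeling, repeat): maps
## are reproducible without storing per-cell RNG state, and fold noise is
## independent across cells. Trials dropped for missing samples at a cell
## are excluded before undersampling.
decodeEngine <- function(epochs, labelVariable, layout, spec, scheme,
                         nRand = 0, strataVariables = NULL, timesMs = NULL,
                         channels = NULL, seed = scheme@seed,
                         includeObserved = TRUE) {
  if (!labelVariable %in% names(epochs@trials))
    abort("label variable '", labelVariable, "' not found in trial metadata")
  if (!is.null(epochs@trials$valid) && !all(epochs@trials$valid))
    epochs <- selectValidTrials(epochs)
  y <- factor(epochs@trials[[labelVariable]])
  if (nlevels(y) < 2) abort("label variable must have at least 2 classes")
  trialIds <- epochs@trials$trial_id %||% seq_len(nTrials(epochs))
  strata <- if (is.null(strataVariables)) NULL else
    interaction(epochs@trials[strataVariables], drop = TRUE)

  ## labelings: observed first (if requested), then nRand constrained shuffles
  labs <- list()
  if (includeObserved) labs[[1]] <- y
  for (r in seq_len(nRand))
    labs[[length(labs) + 1L]] <-
      constrainedShuffle(y, strata, seed = deriveSeed(seed, 7, r))
  Ymat <- vapply(labs, as.integer, integer(length(y)))
  nLab <- ncol(Ymat)

  ## time centers
  fs <- epochs@fs
  nS <- dim(epochs@data)[3]
  nWin <- windowSamples(spec, fs)
  tAxis <- timesMs(epochs)
  if (is.null(timesMs)) {
    centers <- seq_len(nS)
  } else {
    centers <- vapply(timesMs, function(tm) which.min(abs(tAxis - tm)), integer(1))
  }
  centerTimes <- tAxis[centers]
  winList <- lapply(centers, windowIndicesAt, nWin = nWin, nS = nS,
                    alignment = spec@alignment)

  chIdxAll <- if (is.null(channels)) seq_len(nChannels(epochs)) else {
    if (is.character(channels)) match(channels, channelIds(epochs)) else channels
  }
  nbrList <- neighborIndexList(layout, includeSelf = FALSE)

  nCh <- length(chIdxAll); nT <- length(centers)
  accObs <- matrix(NA_real_, nCh, nT)
  nullMean <- matrix(NA_real_, nCh, nT)
  nullSd <- matrix(NA_real_, nCh, nT)
  nUsed <- matrix(0L, nCh, nT)

  anyMissing <- any(epochs@missingMask)
  for (ci in seq_along(chIdxAll)) {
    cc <- chIdxAll[ci]
    chs <- nbrList[[cc]]
    if (spec@includeCenter) chs <- sort(c(cc, chs))
    if (!length(chs)) next
    for (ti in seq_len(nT)) {
      winIdx <- winList[[ti]]
      if (is.null(winIdx)) next                      # undefined center
      slab <- epochs@data[, chs, winIdx, drop = FALSE]
      X <- matrix(aperm(slab, c(1, 3, 2)), dim(slab)[1], nWin * length(chs))
      if (anyMissing) {
        keep <- which(rowSums(is.na(X)) == 0L)
      } else keep <- seq_len(nrow(X))
      if (length(keep) < nrow(X)) {
        X <- X[keep, , drop = FALSE]
        Ysub <- Ymat[keep, , drop = FALSE]
      } else {
        Ysub <- Ymat
      }
      cellSeed <- deriveSeed(scheme@seed, 97, cc, centers[ti])
      acc <- .gnbCvManyGen(t(X), Ysub, nlevels(y), scheme@nFolds,
                           scheme@nRepeats, scheme@undersample, cellSeed)
      acc[is.nan(acc)] <- NA_real_
      nUsed[ci, ti] <- length(keep)
      if (includeObserved) accObs[ci, ti] <- acc[1]
      if (nRand > 0) {
        nullAcc <- acc[(if (includeObserved) 2 else 1):nLab]
        if (sum(!is.na(nullAcc)) >= 2) {
          nullMean[ci, ti] <- mean(nullAcc, na.rm = TRUE)
          nullSd[ci, ti] <- sd(nullAcc, na.rm = TRUE)
        }
      }
    }
  }

  ids <- channelIds(epochs)[chIdxAll]
  subj <- as.character(epochs@trials$subject[1] %||% "1")
  out <- list()
  if (includeObserved)
    out$map <- new("AccuracyMap", accuracy = accObs, nTrials = nUsed,
                   timesMs = centerTimes, channelIds = ids,
                   variable = labelVariable, subject = subj)
  if (nRand > 0)
    out$null <- new("StratifiedNull", nullMean = nullMean, nullSd = nullSd,
                    nRand = nRand,
                    strata = paste(strataVariables %||% character(), collapse = "*"),
                    timesMs = centerTimes, channelIds = ids,
                    variable = labelVariable)
  out
}

#' Searchlight decoding accuracy map
#'
#' Runs [crossValidate()] on the [searchlightFeatures()] of every requested
#' (channel, time) center. Invalid trials are dropped first; trials with
#' missing samples inside a given searchlight are dropped for that cell
#' only. Centers whose window does not fit inside the epoch are undefined
#' (`NA`), never truncated.
#'
#' @param epochs an [EpochSet-class] (combined planar gradients in the
#'   standard pipeline).
#' @param labelVariable name of the trial label column to decode.
#' @param layout the [SensorLayout-class].
#' @param spec a [SearchlightSpec-class].
#' @param scheme a [CvScheme-class].
#' @param timesMs time points (ms) at which to evaluate; default every
#'   sample.
#' @param channels optional subset of channels (ids or indices).
#' @return an [AccuracyMap-class].
#' @export
decodeMap <- function(epochs, labelVariable, layout,
                      spec = searchlightSpec(), scheme = cvScheme(),
                      timesMs = NULL, channels = NULL) {
  decodeEngine(epochs, labelVariable, layout, spec, scheme,
               nRand = 0, timesMs = timesMs, channels = channels)$map
}
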