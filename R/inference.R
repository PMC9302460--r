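#' Constrained (stratified) label shuffle
#'
#' Permutes class labels uniformly at random within each stratum, leaving
#' the per-stratum label multiset exactly unchanged — no label ever moves
#' across strata. With a single stratum this is an ordinary uniform
#' permutation; with one stratum per trial it is the identity. Used to
#' build nulls that respect nuisance structure: e.g. word-length labels are
#' shuffled within each object category (length is not orthogonal to
#' category), and category labels within joint visual-feature bins (to
#' control low-level visual confounds).
#'
#' @param labels class labels (factor or vector).
#' @param strata stratum assignment per trial (`NULL` = single stratum);
#'   must partition the trials. Strata of size 1 leave their label fixed.
#' @param seed integer seed.
#' @return labels permuted within strata (same type/levels as input).
#' @export
constrainedShuffle <- function(labels, strata = NULL, seed = 1) {
  n <- length(labels)
  if (is.null(strata)) strata <- rep(1L, n)
  if (length(strata) != n) abort("strata must have one entry per trial")
  out <- labels
  withSeed(deriveSeed(seed, 17), {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) > 1)
        out[idx] <- labels[idx][sample.int(length(idx))]
    }
  })
  out
}

#' Build a stratified permutation null of decoding accuracy
#'
#' Recomputes the searchlight decoding map for `nRand` constrained label
#' randomizations and accumulates, per (channel, time) cell, the mean and
#' SD of accuracy under the null hypothesis of label exchangeability within
#' strata. The empirical chance level this yields absorbs any decodable
#' structure carried by the strata themselves.
#'
#' @inheritParams decodeMap
#' @param strataVariables character vector of trial metadata columns whose
#'   interaction defines the shuffle strata (`NULL` = unconstrained).
#' @param nRand number of randomizations (default 100, >= 2).
#' @param seed seed for the randomization stream.
#' @return a [StratifiedNull-class].
#' @export
buildNull <- function(epochs, labelVariable, layout,
                      strataVariables = NULL, spec = searchlightSpec(),
                      scheme = cvScheme(), nRand = 100, timesMs = NULL,
                      channels = NULL, seed = 1) {
  if (nRand < 2) abort("nRand must be >= 2")
  decodeEngine(epochs, labelVariable, layout, spec, scheme,
               nRand = nRand, strataVariables = strataVariables,
               timesMs = timesMs, channels = channels, seed = seed,
               includeObserved = FALSE)$null
}

#' Decode a map together with its stratified null
#'
#' Joint, efficient form of [decodeMap()] + [buildNull()] +
#' [zStandardize()]: each searchlight's feature matrix is extracted once
#' and evaluated for the observed labels and all `nRand` randomizations.
#' This is what the pipeline runs per subject.
#'
#' @inheritParams buildNull
#' @return list with `map` ([AccuracyMap-class]), `null`
#'   ([StratifiedNull-class]) and `z` (channels x time matrix of
#'   Z-standardized accuracies).
#' @export
decodeWithNull <- function(epochs, labelVariable, layout,
                           strataVariables = NULL, spec = searchlightSpec(),
                           scheme = cvScheme(), nRand = 100, timesMs = NULL,
                           channels = NULL, seed = 1) {
  if (nRand < 2) abort("nRand must be >= 2")
  res <- decodeEngine(epochs, labelVariable, layout, spec, scheme,
                      nRand = nRand, strataVariables = strataVariables,
                      timesMs = timesMs, channels = channels, seed = seed,
                      includeObserved = TRUE)
  res$z <- zStandardize(res$map, res$null)
  res
}

#' Z-standardize an accuracy map against its empirical null
#'
#' `Z = (accuracy - null mean) / null SD` per cell: the number of null
#' standard deviations the observed accuracy lies above its empirical
#' chance level. Undefined (`NA`) where the null SD is zero or either input
#' is undefined.
#'
#' @param map an [AccuracyMap-class].
#' @param null a matching [StratifiedNull-class].
#' @return channels x time numeric matrix of Z scores.
#' @export
zStandardize <- function(map, null) {
  if (!identical(dim(map@accuracy), dim(null@nullMean)))
    abort("map and null shapes disagree")
  z <- (map@accuracy - null@nullMean) / null@nullSd
  z[!is.finite(z)] <- NA_real_
  dimnames(z) <- list(map@channelIds, NULL)
  z
}

## Connected components of supra-threshold cells under spatial (neighbor
## channels, same time) + temporal (same channel, consecutive defined time
## columns) adjacency. cells: integer matrix of (channel, time) indices.
spatioTemporalClusters <- function(supra, nbrList) {
  nCh <- nrow(supra); nT <- ncol(supra)
  lab <- matrix(0L, nCh, nT)
  nextLab <- 0L
  idx <- which(supra)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ch <- (cur - 1L) %% nCh + 1L
      tt <- (cur - 1L) %/% nCh + 1L
      cand <- integer()
      if (tt > 1L) cand <- c(cand, cur - nCh)
      if (tt < nT) cand <- c(cand, cur + nCh)
      nb <- nbrList[[ch]]
      if (length(nb)) cand <- c(cand, (tt - 1L) * nCh + nb)
      for (cd in cand) {
        if (supra[cd] && lab[cd] == 0L) {
          lab[cd] <- nextLab
          queue <- c(queue, cd)
        }
      }
    }
  }
  lab
}

## One-sample T per cell (columns of S: cells; rows: subjects), with
## precomputed column sums of squares for speed under sign flips.
groupT <- function(S, q, signs) {
  n <- nrow(S)
  m <- as.vector(crossprod(signs, S)) / n
  v <- (q - n * m^2) / (n - 1)
  v[v <= 0] <- NA_real_
  m / sqrt(v / n)
}

#' Group-level cluster-based permutation test over channels and time
#'
#' Tests, across subjects, where Z-standardized decoding accuracy exceeds
#' its empirical chance level. Per cell a one-sample T statistic of the
#' subject Z scores against 0 is computed; cells with one-sided
#' `p < alphaCluster` (T above the critical t with `n - 1` df) form
#' candidate clusters under spatial + temporal adjacency (the same channel
#' neighbor graph used by the searchlight, plus consecutive time points).
#' Cluster mass is the sum of T over the cluster. The family-wise null is
#' the distribution of the maximum cluster mass under random sign flips of
#' whole-subject maps (exact under exchangeability of signs); p-values use
#' the add-one estimator `(1 + #(null >= observed)) / (1 + nPerm)` and are
#' therefore never exactly zero. Inference is one-sided: only
#' above-chance decoding is tested.
#'
#' @param zMaps list of subject Z matrices (channels x time, identical
#'   grids), or a 3-d array subjects x channels x time.
#' @param layout the [SensorLayout-class] providing spatial adjacency (or a
#'   logical adjacency matrix).
#' @param timesMs time axis of the map columns (for reporting).
#' @param alphaCluster cell-level one-sided alpha forming clusters
#'   (default 0.05).
#' @param nPerm number of sign-flip permutations (default 2000).
#' @param seed integer seed for the permutation stream.
#' @return a [ClusterResult-class].
#' @export
clusterPermutationTest <- function(zMaps, layout, timesMs = NULL,
                                   alphaCluster = 0.05, nPerm = 2000,
                                   seed = 1) {
  if (is.array(zMaps) && length(dim(zMaps)) == 3L) {
    zMaps <- lapply(seq_len(dim(zMaps)[1]), function(s) zMaps[s, , ])
  }
  n <- length(zMaps)
  if (n < 2) abort("need at least 2 subjects")
  dims <- dim(zMaps[[1]])
  for (z in zMaps) if (!identical(dim(z), dims)) abort("maps must share one grid")
  nCh <- dims[1]; nT <- dims[2]
  adj <- if (is.matrix(layout) && is.logical(layout)) layout else neighborMatrix(layout)
  if (nrow(adj) != nCh) abort("adjacency does not match map channels")
  nbrList <- lapply(seq_len(nCh), function(i) which(adj[i, ]))
  if (is.null(timesMs)) timesMs <- seq_len(nT)

  S <- t(vapply(zMaps, as.vector, numeric(nCh * nT)))  # subjects x cells
  defined <- colSums(is.na(S)) == 0L
  S[, !defined] <- 0                                    # excluded below
  q <- colSums(S^2)
  thr <- qt(1 - alphaCluster, df = n - 1)

  maxMass <- function(tvec) {
    supra <- matrix(!is.na(tvec) & tvec > thr & defined, nCh, nT)
    if (!any(supra)) return(list(mass = numeric(), lab = NULL))
    lab <- spatioTemporalClusters(supra, nbrList)
    mass <- vapply(seq_len(max(lab)), function(k) sum(tvec[lab == k]), numeric(1))
    list(mass = mass, lab = lab)
  }

  tObs <- groupT(S, q, rep(1, n))
  obs <- maxMass(tObs)
  nullMax <- withSeed(deriveSeed(seed, 23), {
    vapply(seq_len(nPerm), function(p) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      mm <- maxMass(groupT(S, q, signs))$mass
      if (length(mm)) max(mm) else 0
    }, numeric(1))
  })

  if (length(obs$mass)) {
    ordM <- order(obs$mass, decreasing = TRUE)
    pvals <- vapply(obs$mass, function(m) (1 + sum(nullMax >= m)) / (1 + nPerm),
                    numeric(1))
    clusters <- data.frame(cluster = seq_along(ordM),
                           mass = obs$mass[ordM], p = pvals[ordM])
    relab <- match(seq_along(obs$mass), ordM)
    cellIdx <- which(obs$lab > 0L)
    ch <- (cellIdx - 1L) %% nCh + 1L
    tt <- (cellIdx - 1L) %/% nCh + 1L
    cells <- data.frame(
      cluster = relab[obs$lab[cellIdx]],
      channel = if (is.matrix(layout)) as.character(ch) else channelIds(layout)[ch],
      timeMs = timesMs[tt],
      T = tObs[cellIdx])
    cells <- cells[order(cells$cluster, cells$timeMs), ]
    rownames(cells) <- NULL
  } else {
    clusters <- data.frame(cluster = integer(), mass = numeric(), p = numeric())
    cells <- data.frame(cluster = integer(), channel = character(),
                        timeMs = numeric(), T = numeric())
  }
  new("ClusterResult", cells = cells, clusters = clusters, threshold = thr,
      nPerm = nPerm, nSubjects = n, alphaCluster = alphaCluster)
}
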