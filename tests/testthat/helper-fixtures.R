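# Shared in-code fixtures. Everything is generated; nothing is read from
# disk.

# A star layout: one center channel with exactly `nNeighbors` channels
# placed on a circle inside the neighbor threshold. Useful for pinning the
# searchlight channel-set size exactly.
starLayout <- function(nNeighbors, radius = 1, threshold = 1.5) {
  ang <- 2 * pi * seq_len(nNeighbors) / nNeighbors
  pos <- rbind(c(0, 0), cbind(radius * cos(ang), radius * sin(ang)))
  new("SensorLayout",
      channelIds = sprintf("ch%03d", seq_len(nNeighbors + 1)),
      positions = pos, neighborThreshold = threshold)
}

# Small epochs with arbitrary data for structural tests.
toyEpochs <- function(nTrials = 20, layout = makeGridLayout(3, 3),
                      nSamples = 60, fs = 300, t0Ms = -100, seed = 1,
                      labels = NULL) {
  set.seed(seed)
  data <- array(rnorm(nTrials * nChannels(layout) * nSamples),
                dim = c(nTrials, nChannels(layout), nSamples))
  trials <- data.frame(trial_id = seq_len(nTrials), subject = 1,
                       valid = TRUE)
  if (!is.null(labels)) trials$label <- labels
  epochSet(data, fs = fs, t0Ms = t0Ms, trials = trials,
           channelIds = channelIds(layout))
}

# Independent brute-force Gaussian naive Bayes (the oracle): plain loops,
# no shared code with the package implementation beyond the documented
# model (ML variances, relative variance floor, frequency priors,
# first-class tie-break).
bruteGnb <- function(Xtr, ytr, Xte, varFloorFactor = 1e-9) {
  ytr <- factor(ytr)
  K <- nlevels(ytr)
  p <- ncol(Xtr)
  mu <- matrix(NA_real_, K, p)
  vv <- matrix(NA_real_, K, p)
  pr <- numeric(K)
  for (k in seq_len(K)) {
    rows <- which(ytr == levels(ytr)[k])
    pr[k] <- length(rows) / length(ytr)
    for (j in seq_len(p)) {
      xs <- Xtr[rows, j]
      mu[k, j] <- sum(xs) / length(xs)
      vv[k, j] <- sum((xs - mu[k, j])^2) / length(xs)
    }
  }
  eps <- varFloorFactor * mean(vv)
  if (eps <= 0) eps <- 1e-12
  vv[vv < eps] <- eps
  ll <- matrix(NA_real_, nrow(Xte), K)
  for (i in seq_len(nrow(Xte))) {
    for (k in seq_len(K)) {
      s <- log(pr[k])
      for (j in seq_len(p))
        s <- s + stats::dnorm(Xte[i, j], mu[k, j], sqrt(vv[k, j]), log = TRUE)
      ll[i, k] <- s
    }
  }
  post <- t(apply(ll, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  pred <- factor(levels(ytr)[apply(ll, 1, which.max)], levels = levels(ytr))
  list(loglik = ll, posterior = post, predicted = pred)
}
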