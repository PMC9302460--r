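# Single-trial EpochSet holding given per-channel series (channels x samples).
seriesEpochs <- function(series, fs, t0Ms = 0) {
  nCh <- nrow(series)
  data <- array(0, dim = c(1, nCh, ncol(series)))
  data[1, , ] <- series
  epochSet(data, fs = fs, t0Ms = t0Ms,
           trials = data.frame(trial_id = 1, valid = TRUE),
           channelIds = sprintf("ch%03d", seq_len(nCh)))
}

fftAmplitude <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  sp[round(freq * n / fs) + 1]
}

test_that("downsampling 1200 to 300 Hz reduces the sample count by 4", {
  n <- 1321  # -100..1000 ms at 1200 Hz
  ep <- seriesEpochs(matrix(rnorm(n), 1), fs = 1200, t0Ms = -100)
  out <- bandpassDownsample(ep, 1, 30, targetFs = 300)
  expect_equal(nSamples(out), ceiling(n / 4))
  expect_equal(samplingRate(out), 300)
})

test_that("in-band sinusoids pass and out-of-band sinusoids are strongly attenuated", {
  fs <- 1200
  t <- seq(0, 4, by = 1 / fs)  # long window so FFT bins align
  s10 <- sin(2 * pi * 10 * t)
  s100 <- sin(2 * pi * 100 * t)
  ep <- seriesEpochs(rbind(s10, s100), fs = fs)
  out <- bandpassDownsample(ep, 1, 30, targetFs = 300)
  y10 <- epochData(out)[1, 1, ]
  y100 <- epochData(out)[1, 2, ]
  # FFT amplitude oracle at the tone frequency (filter edges trimmed; the
  # trimmed length is a whole number of cycles for both tones)
  trim <- 151:(150 + 900)
  a10 <- fftAmplitude(y10[trim], 300, 10)
  expect_lt(abs(a10 - 1), 0.05)            # unit input amplitude preserved
  a100 <- fftAmplitude(y100[trim], 300, 100)
  expect_lt(20 * log10(a100 / 1), -20)     # >= 20 dB attenuation
})

test_that("trial order does not interact with filtering or the planar transform", {
  lay <- makeGridLayout(3, 3, 1)
  ep <- toyEpochs(8, lay, nSamples = 64, fs = 1200, seed = 12)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  epPerm <- epochSet(epochData(ep)[perm, , , drop = FALSE], 1200, -100,
                     trialInfo(ep)[perm, , drop = FALSE], channelIds(ep))
  pipe <- function(e) epochData(combinePlanar(planarGradient(
    bandpassDownsample(e, 1, 30, targetFs = 300), lay)))
  expect_equal(pipe(epPerm), pipe(ep)[perm, , , drop = FALSE],
               tolerance = 1e-12)
})

test_that("band edges are validated", {
  ep <- seriesEpochs(matrix(rnorm(400), 1), fs = 1200)
  expect_error(bandpassDownsample(ep, 30, 1, 300), "low < high")
  expect_error(bandpassDownsample(ep, 1, 200, targetFs = 300), "Nyquist")
  expect_error(bandpassDownsample(ep, 1, 30, targetFs = 500), "divide")
})

test_that("missing samples propagate conservatively through decimation", {
  n <- 40
  ep <- seriesEpochs(matrix(rnorm(n), 1), fs = 1200)
  mask <- array(FALSE, dim = c(1, 1, n))
  mask[1, 1, 6] <- TRUE  # source sample 6 -> block 2 (samples 5..8)
  ep2 <- epochSet(epochData(ep), 1200, 0, trialInfo(ep),
                  channelIds(ep), missingMask = mask)
  out <- bandpassDownsample(ep2, 1, 30, targetFs = 300)
  expect_true(missingMask(out)[1, 1, 2])
  expect_true(is.na(epochData(out)[1, 1, 2]))
  expect_equal(sum(missingMask(out)), 1)
})

test_that("planar gradient of a uniform field is zero and linear fields are recovered", {
  lay <- makeGridLayout(4, 4, 1)
  nS <- 20
  mkEp <- function(values) {  # values: per-channel constants
    data <- array(rep(rep(values, each = 1), times = nS),
                  dim = c(1, 16, nS))
    for (ch in 1:16) data[1, ch, ] <- values[ch]
    epochSet(data, 300, 0, data.frame(trial_id = 1, valid = TRUE),
             channelIds(lay))
  }
  pl0 <- planarGradient(mkEp(rep(3.7, 16)), lay)
  expect_true(all(abs(pl0@h) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(pl0@v) < 1e-12, na.rm = TRUE))
  pos <- sensorPositions(lay)
  alpha <- 1.9
  pl <- planarGradient(mkEp(alpha * pos[, 1]), lay)
  interior <- which(rowSums(neighborMatrix(lay)) == 4)
  for (ch in interior) {
    expect_equal(pl@h[1, ch, 5], alpha, tolerance = 1e-10)
    expect_equal(pl@v[1, ch, 5], 0, tolerance = 1e-10)
  }
})

test_that("the planar transform is linear in the field", {
  lay <- makeGridLayout(3, 3, 1)
  set.seed(5)
  mk <- function(arr) epochSet(arr, 300, 0,
                               data.frame(trial_id = 1:2, valid = TRUE),
                               channelIds(lay))
  F1 <- array(rnorm(2 * 9 * 10), dim = c(2, 9, 10))
  F2 <- array(rnorm(2 * 9 * 10), dim = c(2, 9, 10))
  a <- 2.5; b <- -1.25
  pl <- planarGradient(mk(a * F1 + b * F2), lay)
  p1 <- planarGradient(mk(F1), lay)
  p2 <- planarGradient(mk(F2), lay)
  expect_equal(pl@h, a * p1@h + b * p2@h, tolerance = 1e-10)
  expect_equal(pl@v, a * p1@v + b * p2@v, tolerance = 1e-10)
})

test_that("isolated channels are flagged and masked missing samples spread to neighbors", {
  lay <- makeGridLayout(3, 3, 1)
  # shrink threshold for one test: place one channel far away
  pos <- rbind(sensorPositions(makeGridLayout(2, 2, 1)), c(10, 10))
  lay5 <- new("SensorLayout", channelIds = sprintf("ch%03d", 1:5),
              positions = pos, neighborThreshold = 1.2)
  data <- array(rnorm(1 * 5 * 8), dim = c(1, 5, 8))
  ep <- epochSet(data, 300, 0, data.frame(trial_id = 1, valid = TRUE),
                 channelIds(lay5))
  expect_warning(pl <- planarGradient(ep, lay5), "isolated")
  expect_true(all(is.na(pl@h[1, 5, ])))
  # missing cell on a channel propagates to its neighbors' components
  mask <- array(FALSE, dim = c(1, 9, 8)); mask[1, 5, 3] <- TRUE
  data9 <- array(rnorm(72), dim = c(1, 9, 8))
  ep9 <- epochSet(data9, 300, 0, data.frame(trial_id = 1, valid = TRUE),
                  channelIds(lay), missingMask = mask)
  pl9 <- planarGradient(ep9, lay)
  nb <- which(neighborMatrix(lay)[5, ])
  expect_true(all(is.na(pl9@h[1, c(5, nb), 3])))
  expect_false(any(is.na(pl9@h[1, setdiff(1:9, c(5, nb)), 3])))
})

test_that("combined planar values follow the Euclidean norm", {
  lay <- makeGridLayout(2, 2, 1)
  pl <- planarGradient(toyEpochs(2, lay, nSamples = 6), lay)
  pl@h[] <- 3; pl@v[] <- 4
  expect_true(all(epochData(combinePlanar(pl)) == 5))
  pl@v[] <- 0; pl@h[] <- -2.5
  expect_true(all(epochData(combinePlanar(pl)) == 2.5))
  # rotation invariance
  set.seed(6)
  pl@h[] <- rnorm(length(pl@h)); pl@v[] <- rnorm(length(pl@v))
  theta <- 0.83
  rot <- pl
  rot@h <- cos(theta) * pl@h - sin(theta) * pl@v
  rot@v <- sin(theta) * pl@h + cos(theta) * pl@v
  expect_equal(epochData(combinePlanar(rot)), epochData(combinePlanar(pl)),
               tolerance = 1e-12)
  expect_true(all(epochData(combinePlanar(pl)) >= 0))
})

test_that("valid-trial selection keeps exactly the flagged trials", {
  lay <- makeGridLayout(2, 2, 1)
  ep <- toyEpochs(10, lay, nSamples = 5)
  expect_identical(selectValidTrials(ep), ep)  # all valid -> identity
  ep@trials$valid <- rep(c(TRUE, FALSE), 5)
  out <- selectValidTrials(ep)
  expect_equal(nTrials(out), 5)
  expect_equal(trialInfo(out)$trial_id, c(1, 3, 5, 7, 9))
  expect_equal(epochData(out)[2, , ], epochData(ep)[3, , ])
  ep@trials$valid <- FALSE
  expect_error(selectValidTrials(ep), "no valid trials")
})
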