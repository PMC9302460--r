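#' Construct an EffectSpec
#'
#' @param variable trial label column the effect encodes (e.g. "category").
#' @param channels channel ids carrying the effect.
#' @param windowMs numeric `[start, end]` in ms relative to stimulus onset.
#' @param amplitudes named numeric vector of per-class signal offsets
#'   (signal units); at least two distinct values.
#' @param waveform envelope identifier, `"halfcosine"` (sustained offset,
#'   default) or `"burst"` (10 Hz oscillatory transient; see
#'   [EffectSpec-class]).
#' @return an [EffectSpec-class].
#' @export
effectSpec <- function(variable, channels, windowMs, amplitudes,
                       waveform = "halfcosine") {
  new("EffectSpec", variable = variable, channels = channels,
      windowMs = as.numeric(windowMs), amplitudes = amplitudes,
      waveform = waveform)
}

#' Construct an EpochSet
#'
#' Low-level constructor; most users obtain EpochSets from
#' [simulateEpochs()] or the preprocessing functions. Cells flagged missing
#' are also set to `NA` in the data.
#'
#' @param data trials x channels x samples numeric array.
#' @param fs sampling rate (Hz).
#' @param t0Ms time of the first sample (ms relative to stimulus onset).
#' @param trials per-trial metadata data.frame (a `valid` logical column is
#'   added if absent).
#' @param channelIds channel labels; defaults from `dimnames(data)[[2]]`.
#' @param missingMask logical array like `data`; defaults to `is.na(data)`.
#' @param metadata free-form provenance list.
#' @return an [EpochSet-class].
#' @export
epochSet <- function(data, fs, t0Ms, trials, channelIds = NULL,
                     missingMask = NULL, metadata = list()) {
  if (is.null(channelIds)) {
    channelIds <- dimnames(data)[[2]] %||% sprintf("ch%03d", seq_len(dim(data)[2]))
  }
  if (is.null(missingMask)) missingMask <- is.na(data)
  missingMask <- missingMask | is.na(data)
  data[missingMask] <- NA_real_
  if (is.null(trials$valid)) trials$valid <- TRUE
  new("EpochSet", data = data, fs = fs, t0Ms = t0Ms, trials = trials,
      missingMask = missingMask, channelIds = channelIds, metadata = metadata)
}

## Flat-top envelope with half-cosine on/off ramps (default 10 ms). The
## ramps keep the upper spectral edge below a 30 Hz lowpass; the "burst"
## variant additionally multiplies a 10 Hz carrier so the component has
## essentially no energy below 1 Hz either (a sustained offset has strong
## DC content inside its window, which a zero-phase 1 Hz highpass would
## smear far outside the window).
effectEnvelope <- function(nSamplesWin, fs, waveform = "halfcosine",
                           rampMs = 10, carrierHz = 10) {
  env <- rep(1, nSamplesWin)
  nRamp <- min(round(rampMs * fs / 1000), floor(nSamplesWin / 2))
  if (nRamp > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nRamp) / (nRamp + 1)))
    env[seq_len(nRamp)] <- ramp
    env[nSamplesWin + 1 - seq_len(nRamp)] <- rev(ramp)
  }
  if (waveform == "burst")
    env <- env * sin(2 * pi * carrierHz * (seq_len(nSamplesWin) - 1L) / fs)
  env
}

#' Simulate epoched MEG-like data with injected class effects
#'
#' Generates one [EpochSet-class] per subject. Each trial is white Gaussian
#' noise per channel (SD `noiseSd`); for every [EffectSpec-class], the
#' class amplitude times a smooth flat-top envelope is added on the effect's
#' channels inside its window. A fraction of trials is flagged invalid
#' (emulating naming errors and disfluencies excluded from analysis,
#' default 17%), and a fraction of trial-channel pairs receives a masked
#' artifact segment (stored as `NA` plus mask). The injected effects are
#' recorded in each EpochSet's `metadata$effects` as retrievable ground
#' truth.
#'
#' @param table stimulus table from [makeStimulusTable()]; its label
#'   columns are replicated into the trial metadata.
#' @param layout a [SensorLayout-class].
#' @param effects list of [EffectSpec-class] objects (possibly empty).
#' @param noiseSd noise standard deviation, >= 0.
#' @param nSubjects number of subjects.
#' @param nReps stimulus repetitions per subject (default 3).
#' @param fs sampling rate in Hz (default 300, the rate after downsampling
#'   a 1200 Hz acquisition by 4).
#' @param epochMs epoch limits in ms relative to stimulus onset
#'   (default `c(-100, 1000)`).
#' @param invalidFraction fraction of trials flagged invalid (default 0.17:
#'   3% naming errors + 14% disfluencies).
#' @param maskFraction fraction of (trial, channel) pairs receiving a
#'   masked artifact segment (default 0.005).
#' @param maskDurationMs duration of each masked segment (default 60 ms).
#' @param seed integer root seed; per-subject streams are derived from it,
#'   so `subjects = 3` reproduces subject 3 of a larger call bit-identically.
#' @param subjects integer vector of subject ids to generate
#'   (default `1:nSubjects`).
#' @return list of [EpochSet-class], one per requested subject.
#' @export
simulateEpochs <- function(table, layout, effects = list(), noiseSd = 1,
                           nSubjects = 12, nReps = 3, fs = 300,
                           epochMs = c(-100, 1000), invalidFraction = 0.17,
                           maskFraction = 0.005, maskDurationMs = 60,
                           seed = 1, subjects = seq_len(nSubjects)) {
  assertScalarNumber(fs, "fs", positive = TRUE)
  if (noiseSd < 0) abort("noiseSd must be >= 0")
  if (invalidFraction < 0 || invalidFraction >= 1)
    abort("invalidFraction must be in [0, 1)")
  nCh <- nChannels(layout)
  nS <- floor((epochMs[2] - epochMs[1]) * fs / 1000) + 1L
  tAxis <- epochMs[1] + (seq_len(nS) - 1L) * 1000 / fs
  ## validate effects up front
  for (ef in effects) {
    stopifnot(is(ef, "EffectSpec"))
    if (!all(ef@channels %in% channelIds(layout)))
      abort("effect on '", ef@variable, "' references unknown channel(s)")
    if (!ef@variable %in% names(table))
      abort("effect variable '", ef@variable, "' not found in stimulus table")
    if (ef@windowMs[1] < epochMs[1] || ef@windowMs[2] > epochMs[2])
      abort("effect window for '", ef@variable, "' lies outside the epoch")
    lev <- levels(factor(table[[ef@variable]]))
    if (!all(lev %in% names(ef@amplitudes)))
      abort("amplitudes for '", ef@variable, "' must name every class level")
  }
  nItems <- nrow(table)
  nTr <- nItems * nReps
  labelCols <- intersect(
    c("item", "word", "category", "n_syllables", "n_phon_neighbors",
      "frequency", "length_class", "density_class",
      "contrast_bin", "edge_density_bin", "colorfulness_bin"),
    names(table))
  lapply(subjects, function(s) {
    withSeed(deriveSeed(seed, 101, s), {
      ord <- sample(rep(seq_len(nItems), nReps))
      trials <- table[ord, labelCols, drop = FALSE]
      trials$repetition <- as.integer(stats::ave(ord, ord, FUN = seq_along))
      trials$subject <- s
      trials$trial_id <- seq_len(nTr)
      rownames(trials) <- NULL
      data <- array(rnorm(nTr * nCh * nS, sd = noiseSd), dim = c(nTr, nCh, nS))
      for (ef in effects) {
        winIdx <- which(tAxis >= ef@windowMs[1] & tAxis <= ef@windowMs[2])
        env <- effectEnvelope(length(winIdx), fs, ef@waveform)
        chIdx <- match(ef@channels, channelIds(layout))
        amp <- ef@amplitudes[as.character(trials[[ef@variable]])]
        ## outer product trial-amplitude x envelope, broadcast over channels
        add <- outer(amp, env)            # nTr x length(winIdx)
        for (ci in chIdx)
          data[, ci, winIdx] <- data[, ci, winIdx] + add
      }
      ## invalid trials (naming errors / disfluencies)
      nInvalid <- round(invalidFraction * nTr)
      valid <- rep(TRUE, nTr)
      if (nInvalid > 0) valid[sample(nTr, nInvalid)] <- FALSE
      trials$valid <- valid
      ## masked artifact segments on random (trial, channel) pairs
      mask <- array(FALSE, dim = c(nTr, nCh, nS))
      nSeg <- round(maskFraction * nTr * nCh)
      if (nSeg > 0) {
        segLen <- max(1L, round(maskDurationMs * fs / 1000))
        pair <- cbind(sample(nTr, nSeg, replace = TRUE),
                      sample(nCh, nSeg, replace = TRUE))
        starts <- sample(max(1L, nS - segLen + 1L), nSeg, replace = TRUE)
        for (k in seq_len(nSeg)) {
          idx <- starts[k]:min(nS, starts[k] + segLen - 1L)
          mask[pair[k, 1], pair[k, 2], idx] <- TRUE
        }
        data[mask] <- NA_real_
      }
      epochSet(data, fs = fs, t0Ms = epochMs[1], trials = trials,
               channelIds = channelIds(layout), missingMask = mask,
               metadata = list(effects = effects, seed = seed, subject = s,
                               noiseSd = noiseSd,
                               invalidFraction = invalidFraction))
    })
  })
}

#' Serialize an EpochSet to plain-text files
#'
#' Writes the data as a flat TSV matrix (`trials * channels` rows x
#' `samples` columns, trial-major), the trial table as TSV, and a JSON
#' sidecar holding `fs`, `t0_ms`, `channel_ids` and dimensions. Masked
#' cells appear as `NA` in the data file.
#'
#' @param epochs an [EpochSet-class].
#' @param prefix path prefix; files `<prefix>_data.tsv`,
#'   `<prefix>_trials.tsv` and `<prefix>_meta.json` are written.
#' @return invisibly, the three file paths.
#' @export
writeEpochSet <- function(epochs, prefix) {
  d <- dim(epochs@data)
  flat <- matrix(aperm(epochs@data, c(2, 1, 3)), d[1] * d[2], d[3])
  dataFile <- paste0(prefix, "_data.tsv")
  trialFile <- paste0(prefix, "_trials.tsv")
  metaFile <- paste0(prefix, "_meta.json")
  write.table(flat, dataFile, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(epochs@trials, trialFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(fs = epochs@fs, t0_ms = epochs@t0Ms,
         channel_ids = epochs@channelIds,
         n_trials = d[1], n_channels = d[2], n_samples = d[3],
         layout = "trial-major rows: (trial 1 ch 1..C, trial 2 ch 1..C, ...)"),
    metaFile, auto_unbox = TRUE, digits = NA)
  invisible(c(data = dataFile, trials = trialFile, meta = metaFile))
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(read.table(paste0(prefix, "_data.tsv"), sep = "\t"))
  trials <- read.table(paste0(prefix, "_trials.tsv"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  d <- c(meta$n_trials, meta$n_channels, meta$n_samples)
  data <- aperm(array(flat, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  epochSet(data, fs = meta$fs, t0Ms = meta$t0_ms, trials = trials,
           channelIds = meta$channel_ids)
}
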