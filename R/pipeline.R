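#' Construct a pipeline configuration
#'
#' Bundles every stage parameter behind a single root seed. All defaults
#' are the package's scaled-down demo geometry: an 8 x 8 sensor grid,
#' 60 items x 3 repetitions, 12 subjects, and three injected effects with
#' sequential latencies (object category 150-250 ms, word length
#' 250-350 ms, neighborhood density 350-450 ms) in distinct sensor regions
#' — the qualitative posterior-to-anterior cascade the pipeline should
#' recover.
#'
#' @param nSubjects,nItems,nReps generator sample sizes.
#' @param gridRows,gridCols,spacing sensor grid geometry.
#' @param effects list of [EffectSpec-class] (or lists with fields
#'   `variable`, `channels`, `windowMs`, `amplitudes`, as parsed from
#'   YAML); `NULL` = the three-effect demo; `list()` = no effects.
#' @param noiseSd generator noise SD.
#' @param fs sampling rate (Hz).
#' @param epochMs epoch limits (ms).
#' @param invalidFraction fraction of trials flagged invalid.
#' @param bandpass apply the 1-30 Hz zero-phase bandpass (default TRUE).
#' @param planar apply the planar gradient transform + combination
#'   (default TRUE).
#' @param variables named list mapping each decoded variable to its shuffle
#'   strata (character vector or NULL). Default: category is shuffled
#'   within joint visual-feature bins (controlling low-level visual
#'   confounds), and each of the two correlated phonological variables is
#'   shuffled within object category crossed with the other phonological
#'   variable — word length and neighborhood density are strongly
#'   correlated across items, so a null stratified by category alone would
#'   leave each variable decodable through the other's effect.
#' @param windowMs,alignment,includeCenter searchlight geometry.
#' @param timesMs decoding time points (ms); default `seq(0, 600, 50)`.
#' @param nFolds,nRepeats cross-validation scheme.
#' @param nRand randomizations per subject null (default 100).
#' @param nPerm group permutations (default 2000).
#' @param alphaCluster cluster-forming alpha (default 0.05).
#' @param outputDir optional directory for TSV outputs.
#' @param seed root integer seed.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(nSubjects = 12, nItems = 60, nReps = 3,
                           gridRows = 8, gridCols = 8, spacing = 1,
                           effects = NULL, noiseSd = 1, fs = 300,
                           epochMs = c(-100, 1000), invalidFraction = 0.17,
                           bandpass = TRUE, planar = TRUE,
                           variables = NULL,
                           windowMs = 150, alignment = "centered",
                           includeCenter = TRUE,
                           timesMs = seq(0, 600, by = 50),
                           nFolds = 5, nRepeats = 5, nRand = 100,
                           nPerm = 2000, alphaCluster = 0.05,
                           outputDir = "", seed = 1) {
  if (is.null(effects)) effects <- demoEffects(gridRows, gridCols)
  effects <- lapply(effects, asEffectSpec)
  if (is.null(variables)) {
    variables <- list(
      category = c("contrast_bin", "edge_density_bin", "colorfulness_bin"),
      length_class = c("category", "density_class"),
      density_class = c("category", "length_class"))
  }
  new("PipelineConfig",
      generator = list(nSubjects = nSubjects, nItems = nItems, nReps = nReps,
                       gridRows = gridRows, gridCols = gridCols,
                       spacing = spacing, effects = effects,
                       noiseSd = noiseSd, fs = fs, epochMs = epochMs,
                       invalidFraction = invalidFraction),
      preprocessing = list(bandpass = bandpass, low = 1, high = 30,
                           planar = planar),
      searchlight = list(windowMs = windowMs, alignment = alignment,
                         includeCenter = includeCenter, timesMs = timesMs),
      decoding = list(variables = variables, nFolds = nFolds,
                      nRepeats = nRepeats),
      inference = list(nRand = nRand, nPerm = nPerm,
                       alphaCluster = alphaCluster),
      outputDir = outputDir, seed = seed)
}

asEffectSpec <- function(x) {
  if (is(x, "EffectSpec")) return(x)
  effectSpec(variable = x$variable, channels = unlist(x$channels),
             windowMs = unlist(x$windowMs),
             amplitudes = unlist(x$amplitudes),
             waveform = x$waveform %||% "halfcosine")
}

## The three-effect demo ground truth: sequential windows in distinct grid
## regions (posterior block -> left mid block -> anterior block on the
## flattened grid). Amplitudes are moderate on purpose: with unit noise
## they yield in-window decoding accuracies a few tens of percentage
## points above chance at most — effects strong enough to recover at
## desk scale, while keeping off-window cells at chance (very strong
## offsets would leak decodable filter ringing across the epoch).
demoEffects <- function(gridRows = 8, gridCols = 8) {
  chId <- function(rows, cols) {
    sprintf("ch%03d", as.vector(outer(cols, (rows - 1) * gridCols, "+")))
  }
  list(
    effectSpec("category", chId(1:3, 2:4), c(150, 250),
               c(animal = 0, food = 0.4, tool = 0.8, clothes = 1.2),
               waveform = "burst"),
    effectSpec("length_class", chId(4:6, 1:3), c(250, 350),
               c(short = 0, long = 0.5), waveform = "burst"),
    effectSpec("density_class", chId(7:8, 5:8), c(350, 450),
               c(smaller = 0, small = 0.4, large = 0.8, larger = 1.2),
               waveform = "burst")
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [PipelineConfig-class].
#' @return `readPipelineConfig` returns a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- c(y$generator, y$preprocessing, y$searchlight, y$decoding,
            y$inference)
  args$low <- NULL; args$high <- NULL
  args$outputDir <- y$outputDir %||% ""
  args$seed <- y$seed %||% 1
  do.call(pipelineConfig, args)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  g <- config@generator
  g$effects <- lapply(g$effects, function(e)
    list(variable = e@variable, channels = e@channels,
         windowMs = e@windowMs, amplitudes = as.list(e@amplitudes),
         waveform = e@waveform))
  yaml::write_yaml(list(generator = g,
                        preprocessing = config@preprocessing,
                        searchlight = config@searchlight,
                        decoding = config@decoding,
                        inference = config@inference,
                        outputDir = config@outputDir,
                        seed = config@seed), path)
  invisible(path)
}

#' Run the full simulate - preprocess - decode - infer pipeline
#'
#' Executes, per subject: simulation (or uses `epochsList` if supplied),
#' optional bandpass, planar gradient transform + combination, valid-trial
#' selection, then per decoded variable the searchlight decoding map with
#' its stratified null and Z-standardization; finally the group-level
#' cluster permutation test per variable, and a recovery report comparing
#' significant clusters to the injected ground truth (onset error in ms,
#' channel-set Jaccard overlap). Fully deterministic given the config.
#'
#' @param config a [PipelineConfig-class].
#' @param epochsList optional list of [EpochSet-class] (one per subject) to
#'   use instead of simulating.
#' @param verbose print per-stage progress (default TRUE).
#' @return object of class `PipelineResult`: list with `config`, `layout`,
#'   `table`, `zMaps` (variable -> subjects x channels x time array),
#'   `accMaps`, `clusterResults`, `recovery`, `timesMs`.
#' @export
runPipeline <- function(config, epochsList = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  g <- config@generator
  layout <- makeGridLayout(g$gridRows, g$gridCols, g$spacing)
  table <- makeStimulusTable(g$nItems, seed = deriveSeed(config@seed, 1))
  vars <- names(config@decoding$variables)
  say("pipeline: %d subjects, %d channels, %d items x %d reps, variables: %s",
      g$nSubjects, nChannels(layout), g$nItems, g$nReps,
      paste(vars, collapse = ", "))

  spec <- searchlightSpec(config@searchlight$windowMs,
                          config@searchlight$alignment,
                          config@searchlight$includeCenter)
  tms <- config@searchlight$timesMs
  zMaps <- lapply(vars, function(v) NULL); names(zMaps) <- vars
  accMaps <- lapply(vars, function(v) list()); names(accMaps) <- vars

  for (s in seq_len(g$nSubjects)) {
    ep <- if (!is.null(epochsList)) epochsList[[s]] else
      simulateEpochs(table, layout, effects = g$effects, noiseSd = g$noiseSd,
                     nSubjects = g$nSubjects, nReps = g$nReps, fs = g$fs,
                     epochMs = g$epochMs,
                     invalidFraction = g$invalidFraction,
                     seed = deriveSeed(config@seed, 2), subjects = s)[[1]]
    if (config@preprocessing$bandpass)
      ep <- bandpassDownsample(ep, config@preprocessing$low,
                               config@preprocessing$high)
    if (config@preprocessing$planar)
      ep <- combinePlanar(planarGradient(ep, layout))
    ep <- selectValidTrials(ep)
    for (v in vars) {
      scheme <- cvScheme(config@decoding$nFolds, config@decoding$nRepeats,
                         seed = deriveSeed(config@seed, 3, s, match(v, vars)))
      res <- decodeWithNull(ep, v, layout,
                            strataVariables = config@decoding$variables[[v]],
                            spec = spec, scheme = scheme,
                            nRand = config@inference$nRand, timesMs = tms,
                            seed = deriveSeed(config@seed, 4, s, match(v, vars)))
      accMaps[[v]][[s]] <- res$map
      if (is.null(zMaps[[v]]))
        zMaps[[v]] <- array(NA_real_,
                            dim = c(g$nSubjects, nrow(res$z), ncol(res$z)))
      zMaps[[v]][s, , ] <- res$z
    }
    say("  subject %d/%d decoded", s, g$nSubjects)
  }

  clusterResults <- lapply(vars, function(v)
    clusterPermutationTest(zMaps[[v]], layout, timesMs = tms,
                           alphaCluster = config@inference$alphaCluster,
                           nPerm = config@inference$nPerm,
                           seed = deriveSeed(config@seed, 5, match(v, vars))))
  names(clusterResults) <- vars

  recovery <- recoveryReport(clusterResults, g$effects)
  res <- structure(list(config = config, layout = layout, table = table,
                        zMaps = zMaps, accMaps = accMaps,
                        clusterResults = clusterResults,
                        recovery = recovery, timesMs = tms),
                   class = "PipelineResult")
  if (nzchar(config@outputDir)) writePipelineOutputs(res, config@outputDir)
  res
}

## Compare significant clusters (p < 0.05) to the injected ground truth.
## Each effect is matched to the significant cluster of its variable with
## the highest channel-set Jaccard overlap against the injected channels
## (a variable whose labels correlate with another manipulated variable
## can yield additional genuine clusters at the other effect's site; those
## are counted in nSignificant but should not define this effect's
## recovery). The recovered onset is the earliest time at which the
## matched cluster holds a substantial share of its peak spatial extent
## (at least 25% of the maximum per-time cell count, and no fewer than 2
## cells): cluster-based tests are prone to small excursions at the
## cluster-forming threshold, and a marginal bridge of a cell or two
## should not define when an effect begins.
recoveryReport <- function(clusterResults, effects) {
  if (!length(effects)) return(data.frame())
  rows <- lapply(effects, function(ef) {
    v <- ef@variable
    cr <- clusterResults[[v]]
    out <- data.frame(variable = v, injectedOnsetMs = ef@windowMs[1],
                      recoveredOnsetMs = NA_real_, onsetErrorMs = NA_real_,
                      jaccard = NA_real_, nSignificant = 0L)
    if (is.null(cr)) return(out)
    sig <- clusterTable(cr)$cluster[clusterTable(cr)$p < 0.05]
    out$nSignificant <- length(sig)
    if (length(sig)) {
      cells <- clusterCells(cr)
      jacc <- vapply(sig, function(k) {
        chans <- unique(cells$channel[cells$cluster == k])
        length(intersect(chans, ef@channels)) /
          length(union(chans, ef@channels))
      }, numeric(1))
      best <- sig[which.max(jacc)]
      out$jaccard <- max(jacc)
      bestCells <- cells[cells$cluster == best, ]
      perTime <- table(bestCells$timeMs)
      minCells <- max(2, ceiling(0.25 * max(perTime)))
      solid <- as.numeric(names(perTime)[perTime >= minCells])
      out$recoveredOnsetMs <- if (length(solid)) min(solid)
                              else min(bestCells$timeMs)
      out$onsetErrorMs <- out$recoveredOnsetMs - ef@windowMs[1]
    }
    out
  })
  do.call(rbind, rows)
}

#' Summarize a pipeline run
#'
#' Prints, per decoded variable, the peak-accuracy cell, the first
#' significant time point, the cluster table, and the ground-truth recovery
#' metrics (or states that no significant clusters were found).
#'
#' @param results a `PipelineResult` from [runPipeline()].
#' @return invisibly, a list of summary data.frames (`peaks`, `clusters`,
#'   `recovery`).
#' @export
reportPipeline <- function(results) {
  vars <- names(results$clusterResults)
  peaks <- do.call(rbind, lapply(vars, function(v) {
    zbar <- apply(results$zMaps[[v]], c(2, 3), mean)
    pk <- which(zbar == max(zbar, na.rm = TRUE), arr.ind = TRUE)[1, ]
    data.frame(variable = v,
               peakChannel = channelIds(results$layout)[pk[1]],
               peakTimeMs = results$timesMs[pk[2]],
               peakMeanZ = max(zbar, na.rm = TRUE))
  }))
  clusters <- do.call(rbind, lapply(vars, function(v) {
    ct <- clusterTable(results$clusterResults[[v]])
    if (!nrow(ct)) return(NULL)
    cbind(variable = v, ct)
  }))
  cat("Pipeline summary\n================\n")
  for (v in vars) {
    cr <- results$clusterResults[[v]]
    ct <- clusterTable(cr)
    sig <- ct[ct$p < 0.05, , drop = FALSE]
    cat(sprintf("\n%s:\n", v))
    if (nrow(sig)) {
      first <- min(clusterCells(cr)$timeMs[clusterCells(cr)$cluster %in% sig$cluster])
      cat(sprintf("  %d significant cluster(s); first significant time %g ms\n",
                  nrow(sig), first))
      for (i in seq_len(nrow(sig)))
        cat(sprintf("    cluster %d: mass %.1f, p = %.4f\n",
                    sig$cluster[i], sig$mass[i], sig$p[i]))
    } else cat("  no significant clusters\n")
  }
  if (nrow(results$recovery)) {
    cat("\nGround-truth recovery:\n")
    print(results$recovery, row.names = FALSE)
  }
  invisible(list(peaks = peaks, clusters = clusters,
                 recovery = results$recovery))
}

#' Average a map over a named sensor subset
#'
#' Time course of a channels x time matrix averaged over the given
#' channels, the standard reduction for displaying decoding time courses
#' of a sensor region of interest.
#'
#' @param m channels x time matrix (e.g. a Z map or accuracy matrix).
#' @param channelIds row names / layout channel ids of `m`.
#' @param channels subset of channel ids to average over.
#' @return numeric vector, one value per time column.
#' @export
sensorSubsetTimecourse <- function(m, channelIds, channels) {
  idx <- match(channels, channelIds)
  if (anyNA(idx)) abort("unknown channel(s) in subset")
  colMeans(m[idx, , drop = FALSE], na.rm = TRUE)
}

## TSV outputs: long-format accuracy maps, cluster tables, recovery table,
## and a config echo.
writePipelineOutputs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePipelineConfig(results$config, file.path(dir, "config.yaml"))
  for (v in names(results$accMaps)) {
    maps <- results$accMaps[[v]]
    long <- do.call(rbind, lapply(maps, accuracyMapToLong))
    write.table(long, file.path(dir, paste0("accuracy_", v, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cr <- results$clusterResults[[v]]
    write.table(clusterTable(cr),
                file.path(dir, paste0("clusters_", v, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(clusterCells(cr),
                file.path(dir, paste0("cluster_cells_", v, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(results$recovery, file.path(dir, "recovery.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Long-format view of an accuracy map
#'
#' @param map an [AccuracyMap-class].
#' @param file optional TSV path.
#' @return data.frame with columns subject, variable, channel, time_ms,
#'   accuracy, n_trials.
#' @export
accuracyMapToLong <- function(map, file = NULL) {
  df <- data.frame(
    subject = map@subject, variable = map@variable,
    channel = rep(map@channelIds, times = length(map@timesMs)),
    time_ms = rep(map@timesMs, each = length(map@channelIds)),
    accuracy = as.vector(map@accuracy),
    n_trials = as.vector(map@nTrials))
  if (!is.null(file))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
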