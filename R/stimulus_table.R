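## Stimulus table generation.
##
## The generator emulates a picture-naming stimulus set: items from four
## object categories, word length in syllables (mostly mono-/bisyllabic),
## phonological neighborhood density (count of words differing in one
## phone), and SUBTLEX-style word frequency per million. The three lexical
## variables are sampled through a Gaussian copula so their realized
## correlations approach the canonical targets
## (length-density -0.67, frequency-length -0.37, frequency-density +0.32);
## visual features are sampled independently of the lexical variables.

stimulusCategories <- c("animal", "food", "tool", "clothes")

## PSD check with a small tolerance; used to reject infeasible targets and
## to repair calibrated latent matrices.
isPsd <- function(R, tol = 1e-8) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol)
}

makePsd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 1e-6)
  R2 <- e$vectors %*% diag(ev) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2
}

## Marginal transforms from standard-normal latents.
## z1: word length latent (higher -> more syllables);
## z2: density latent (higher -> more neighbors);
## z3: frequency latent (higher -> more frequent).
syllablesFromLatent <- function(z, probs = c(65, 66, 3) / 134) {
  br <- qnorm(cumsum(probs)[-length(probs)])
  1L + findInterval(z, br)
}

densityFromLatent <- function(z) {
  ## negative-binomial marginal, roughly matching published summaries
  ## (mean ~12, SD ~10, median ~9, range 0 to ~46 neighbors)
  qnbinom(pnorm(z), size = 2.2, mu = 12)
}

frequencyFromLatent <- function(z) {
  ## lognormal occurrences per million: median ~4.8, mean ~8.3
  round(qlnorm(pnorm(z), meanlog = 1.57, sdlog = 1.05), 4)
}

defaultCorrelationTargets <- c(
  length_density = -0.67,
  frequency_length = -0.37,
  frequency_density = 0.32
)

latentMatrix <- function(targets) {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- targets[["length_density"]]
  R[1, 3] <- R[3, 1] <- targets[["frequency_length"]]
  R[2, 3] <- R[3, 2] <- targets[["frequency_density"]]
  R
}

sampleLatents <- function(n, R) {
  L <- t(chol(makePsd(R)))
  t(L %*% matrix(rnorm(3 * n), 3, n))
}

realizedCorrelations <- function(tab) {
  c(length_density = cor(tab$n_syllables, tab$n_phon_neighbors),
    frequency_length = cor(log(tab$frequency + 0.01), tab$n_syllables),
    frequency_density = cor(log(tab$frequency + 0.01), tab$n_phon_neighbors))
}

#' Generate a psycholinguistic stimulus table
#'
#' Creates `nItems` picture-naming items spread (balanced up to one item)
#' over four object categories, with syllable counts (1-3, mostly 1-2),
#' phonological neighborhood density counts, and word frequencies per
#' million sampled through a Gaussian copula so that the realized pairwise
#' correlations approach `targets`. The latent correlations are calibrated
#' over a few deterministic refinement passes to counter the attenuation
#' introduced by the discrete marginals. Visual features (contrast, edge
#' density, colorfulness) are sampled independently of the lexical
#' variables.
#'
#' Derived labels are attached for every decoding contrast:
#' `length_class` (short = monosyllabic, long = bi-/trisyllabic),
#' `density_class` (four quantile classes smaller/small/large/larger, ties
#' to the lower class) and low/high median-split bins of each visual
#' feature. Frequency correlations are measured on the log scale, which is
#' how skewed per-million counts are conventionally analyzed.
#'
#' @param nItems number of items, >= 16 (at least 4 per category).
#' @param seed integer seed; the table is a pure function of
#'   `(nItems, seed, targets)`.
#' @param targets named numeric vector of target Pearson correlations with
#'   names `length_density`, `frequency_length`, `frequency_density`.
#'   Rejected when the implied matrix is not positive semidefinite.
#' @return data.frame with one row per item.
#' @examples
#' tab <- makeStimulusTable(134, seed = 1)
#' cor(tab$n_syllables, tab$n_phon_neighbors)  # near -0.67
#' @export
makeStimulusTable <- function(nItems = 134, seed = 1,
                              targets = defaultCorrelationTargets) {
  if (nItems < 16) abort("nItems must be >= 16 (>= 4 items per category)")
  miss <- setdiff(names(defaultCorrelationTargets), names(targets))
  if (length(miss)) abort("targets must name: ", paste(miss, collapse = ", "))
  Rtarget <- latentMatrix(targets)
  if (!isPsd(Rtarget))
    abort("infeasible correlation targets: matrix is not positive semidefinite")
  withSeed(deriveSeed(seed, 11), {
    ## Calibrate the latent correlations against the attenuation the
    ## discrete marginals introduce, on a large latent sample (so the
    ## calibration itself carries negligible Monte-Carlo error), then draw
    ## the table once from the calibrated copula.
    tgt <- targets[names(defaultCorrelationTargets)]
    Rlat <- Rtarget
    nCal <- 4000
    for (iter in 1:3) {
      Zc <- sampleLatents(nCal, Rlat)
      calTab <- data.frame(
        n_syllables = syllablesFromLatent(Zc[, 1]),
        n_phon_neighbors = densityFromLatent(Zc[, 2]),
        frequency = frequencyFromLatent(Zc[, 3]))
      adj <- tgt - realizedCorrelations(calTab)
      Rlat <- makePsd(latentMatrix(pmin(pmax(
        c(length_density = Rlat[1, 2] + adj[["length_density"]],
          frequency_length = Rlat[1, 3] + adj[["frequency_length"]],
          frequency_density = Rlat[2, 3] + adj[["frequency_density"]]),
        -0.97), 0.97)))
    }
    Z <- sampleLatents(nItems, Rlat)
    tab <- data.frame(
      item = sprintf("item%03d", seq_len(nItems)),
      word = sprintf("word%03d", seq_len(nItems)),
      category = factor(sample(rep_len(stimulusCategories, nItems)),
                        levels = stimulusCategories),
      n_syllables = syllablesFromLatent(Z[, 1]),
      n_phon_neighbors = densityFromLatent(Z[, 2]),
      frequency = frequencyFromLatent(Z[, 3]),
      stringsAsFactors = FALSE
    )
    ## independent visual features
    tab$contrast <- rgamma(nItems, shape = 3, rate = 60)
    tab$edge_density <- runif(nItems, 2, 35)
    tab$colorfulness <- rgamma(nItems, shape = 4, rate = 0.12)
    ## derived class labels
    tab$length_class <- factor(ifelse(tab$n_syllables == 1, "short", "long"),
                               levels = c("short", "long"))
    tab$density_class <- discretizeQuantiles(
      tab$n_phon_neighbors, 4L,
      labels = c("smaller", "small", "large", "larger"))
    for (v in c("contrast", "edge_density", "colorfulness"))
      tab[[paste0(v, "_bin")]] <-
        discretizeQuantiles(tab[[v]], 2L, labels = c("low", "high"))
    tab
  })
}

#' Write / read a stimulus table as TSV
#'
#' @param table stimulus table data.frame.
#' @param file path to a TSV file.
#' @return `readStimulusTable` returns the table with factor label columns
#'   restored.
#' @export
writeStimulusTable <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeStimulusTable
#' @export
readStimulusTable <- function(file) {
  tab <- read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if ("category" %in% names(tab))
    tab$category <- factor(tab$category, levels = stimulusCategories)
  if ("length_class" %in% names(tab))
    tab$length_class <- factor(tab$length_class, levels = c("short", "long"))
  if ("density_class" %in% names(tab))
    tab$density_class <- factor(tab$density_class,
      levels = c("smaller", "small", "large", "larger"), ordered = TRUE)
  for (v in c("contrast_bin", "edge_density_bin", "colorfulness_bin"))
    if (v %in% names(tab))
      tab[[v]] <- factor(tab[[v]], levels = c("low", "high"), ordered = TRUE)
  tab
}
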