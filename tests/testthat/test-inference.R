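test_that("constrained shuffles conserve per-stratum label multisets exactly", {
  labels <- factor(c("s", "l", "s", "l", "s", "l", "s", "l", "s", "l", "l", "l"))
  strata <- rep(c("animal", "food", "tool"), each = 4)
  for (seed in 1:50) {
    out <- constrainedShuffle(labels, strata, seed = seed)
    for (s in unique(strata)) {
      expect_equal(table(out[strata == s]), table(labels[strata == s]))
    }
  }
  # and labels do move within strata
  moved <- vapply(1:50, function(seed)
    any(constrainedShuffle(labels, strata, seed) != labels), logical(1))
  expect_true(any(moved))
})

test_that("degenerate stratifications behave as specified", {
  labels <- factor(c("a", "b", "b", "a", "b", "a"))
  # single stratum: ordinary permutation (multiset preserved)
  out <- constrainedShuffle(labels, NULL, seed = 2)
  expect_equal(as.vector(table(out)), as.vector(table(labels)))
  # one stratum per trial: identity, always
  for (seed in 1:10)
    expect_identical(constrainedShuffle(labels, seq_along(labels), seed),
                     labels)
  expect_error(constrainedShuffle(labels, 1:3), "one entry per trial")
})

test_that("two three-trial strata realize all within-stratum arrangements and nothing more", {
  labels <- factor(c("a", "a", "b", "a", "b", "b"))
  strata <- rep(1:2, each = 3)
  seen <- unique(vapply(1:300, function(seed)
    paste(constrainedShuffle(labels, strata, seed), collapse = ""),
    character(1)))
  # stratum 1 has 3 arrangements of {a,a,b}, stratum 2 has 3 of {a,b,b}
  expect_setequal(seen, as.vector(outer(c("aab", "aba", "baa"),
                                        c("abb", "bab", "bba"), paste0)))
})

test_that("Z-standardization follows its definition and flags zero-SD cells", {
  mk <- function(acc, nm, ns) {
    map <- new("AccuracyMap", accuracy = acc,
               nTrials = matrix(100L, nrow(acc), ncol(acc)),
               timesMs = seq_len(ncol(acc)) * 10,
               channelIds = sprintf("ch%03d", seq_len(nrow(acc))),
               variable = "v", subject = "1")
    null <- new("StratifiedNull", nullMean = nm, nullSd = ns, nRand = 100,
                strata = "", timesMs = map@timesMs,
                channelIds = map@channelIds, variable = "v")
    zStandardize(map, null)
  }
  acc <- matrix(c(0.25, 0.35, 0.25, 0.5), 2, 2)
  nm <- matrix(0.25, 2, 2)
  ns <- matrix(0.05, 2, 2)
  z <- mk(acc, nm, ns)
  expect_equal(unname(z[1, 1]), 0)      # accuracy at the null mean
  expect_equal(unname(z[2, 1]), 2)      # mean + 2 SD
  expect_equal(unname(z[2, 2]), 5)
  ns[1, 2] <- 0
  expect_true(is.na(mk(acc, nm, ns)[1, 2]))
})

test_that("a stratified null on label-independent data centers at chance", {
  lay <- starLayout(3)
  set.seed(71)
  n <- 80
  labels <- factor(rep(c("a", "b", "c", "d"), 20))
  ep <- toyEpochs(n, lay, nSamples = 60, fs = 300, seed = 72)
  ep@trials$label <- labels
  ep@trials$stratum <- rep(c("x", "y"), each = 40)
  null <- buildNull(ep, "label", lay, strataVariables = "stratum",
                    spec = searchlightSpec(100), scheme = cvScheme(seed = 5),
                    nRand = 40, timesMs = 0, seed = 9)
  expect_equal(null@nRand, 40)
  expect_lt(abs(null@nullMean[1, 1] - 0.25), 0.03)
  expect_gt(null@nullSd[1, 1], 0)
})

test_that("all-zero Z maps produce no clusters", {
  lay <- makeGridLayout(3, 3, 1)
  zMaps <- lapply(1:6, function(s) matrix(0, 9, 5))
  res <- clusterPermutationTest(zMaps, lay, nPerm = 100, seed = 1)
  expect_equal(nrow(clusterTable(res)), 0)
  expect_output(show(res), "no significant clusters")
})

test_that("two disjoint supra-threshold regions form two contiguous clusters", {
  lay <- makeGridLayout(3, 3, 1)
  nT <- 8
  # background alternates +-0.05 across subjects (exact zero mean, so its
  # group T is exactly 0); the two regions sit far above threshold
  mkZ <- function(s) {
    z <- matrix(0.05 * (-1)^s, 9, nT)
    z[c(1, 2), 1:2] <- z[c(1, 2), 1:2] + 5     # region A: channels 1-2, t 1-2
    z[9, 6:8] <- z[9, 6:8] + 5                 # region B: channel 9, t 6-8
    z
  }
  res <- clusterPermutationTest(lapply(1:8, mkZ), lay,
                                timesMs = (1:nT) * 10, nPerm = 200, seed = 2)
  ct <- clusterTable(res)
  expect_equal(nrow(ct), 2)
  expect_true(all(diff(ct$p) >= 0))  # p non-increasing in mass
  cells <- clusterCells(res)
  a <- cells[cells$channel %in% c("ch001", "ch002"), ]
  b <- cells[cells$channel == "ch009", ]
  expect_equal(length(unique(a$cluster)), 1)
  expect_equal(length(unique(b$cluster)), 1)
  expect_false(unique(a$cluster) == unique(b$cluster))
  expect_setequal(a$timeMs, c(10, 20))
  expect_setequal(b$timeMs, c(60, 70, 80))
})

test_that("shifting all subject maps by a constant keeps the permutation test coherent", {
  lay <- makeGridLayout(3, 3, 1)
  set.seed(91)
  zMaps <- lapply(1:8, function(s) matrix(rnorm(9 * 6, 0, 1), 9, 6))
  base <- clusterPermutationTest(zMaps, lay, nPerm = 300, seed = 4)
  shifted <- clusterPermutationTest(lapply(zMaps, function(z) z + 1.5),
                                    lay, nPerm = 300, seed = 4)
  # the shift raises every cell's T, so the supra-threshold set can only
  # grow, and the null (recomputed from the shifted maps under sign flips)
  # still yields valid add-one p-values
  expect_gte(nrow(clusterCells(shifted)), nrow(clusterCells(base)))
  ct <- clusterTable(shifted)
  expect_true(all(ct$p > 0 & ct$p <= 1))
  # maps constant across subjects have zero variance: T undefined
  # everywhere, so no clusters can form
  flat <- clusterPermutationTest(lapply(1:8, function(s) matrix(2, 9, 6)),
                                 lay, nPerm = 100, seed = 5)
  expect_equal(nrow(clusterTable(flat)), 0)
})

test_that("cluster inputs are validated and p-values never reach zero", {
  lay <- makeGridLayout(2, 2, 1)
  expect_error(clusterPermutationTest(list(matrix(0, 4, 3)), lay), "2 subjects")
  zMaps <- lapply(1:6, function(s) matrix(rnorm(12, 3, 0.3), 4, 3))
  res <- clusterPermutationTest(zMaps, lay, nPerm = 64, seed = 3)
  ct <- clusterTable(res)
  expect_true(all(ct$p >= 1 / 65))  # add-one estimator floor
})
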