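test_that("GNB fitting recovers class means, variances and priors", {
  X <- matrix(c(-1, -1, 1, 1), 4, 1)
  y <- c("a", "a", "b", "b")
  m <- fitGnb(X, y)
  expect_equal(unname(m$means[, 1]), c(-1, 1))
  expect_equal(m$priors, c(0.5, 0.5))
  X2 <- matrix(c(0, 2, 0, 4, 10, 12), 6, 1)
  m2 <- fitGnb(X2, rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(m2$means[, 1]), c(1, 2, 11))
  expect_equal(unname(m2$vars["a", 1]), 1)  # ML variance, divisor n
  expect_error(fitGnb(matrix(1:3, 3, 1), c("a", "a", "b")), "at least 2 trials")
  expect_error(fitGnb(matrix(1:4, 4, 1), rep("a", 4)), "2 classes")
})

test_that("GNB posteriors equal the brute-force normalized density product", {
  set.seed(11)
  Xtr <- matrix(rnorm(24), 12, 2)
  ytr <- rep(c("a", "b", "c"), each = 4)
  Xte <- matrix(rnorm(10), 5, 2)
  m <- fitGnb(Xtr, ytr)
  oracle <- bruteGnb(Xtr, ytr, Xte)
  expect_equal(unname(predictGnb(m, Xte, type = "posterior")),
               unname(oracle$posterior), tolerance = 1e-12)
  expect_equal(predictGnb(m, Xte), oracle$predicted)
})

test_that("equal-prior equal-variance decision boundary sits midway and ties break canonically", {
  X <- matrix(c(-1, -1.5, -0.5, 1, 1.5, 0.5), 6, 1)
  y <- rep(c("a", "b"), each = 3)
  m <- fitGnb(X, y)
  expect_equal(as.character(predictGnb(m, matrix(-0.01))), "a")
  expect_equal(as.character(predictGnb(m, matrix(0.01))), "b")
  # exactly symmetric point: first class in canonical order wins
  expect_equal(as.character(predictGnb(m, matrix(0))), "a")
  expect_error(predictGnb(m, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("undersampling balances classes and is seed-deterministic", {
  y <- rep(c("a", "b", "c", "d"), times = c(10, 6, 6, 6))
  kept <- undersample(y, seed = 4)
  expect_equal(as.vector(table(y[kept])), c(6, 6, 6, 6))
  expect_identical(kept, undersample(y, seed = 4))
  expect_false(identical(kept, undersample(y, seed = 5)))
  yb <- rep(c("a", "b"), each = 5)
  expect_identical(undersample(yb, 1), 1:10)  # balanced input: all kept
})

test_that("cross-validation plans are stratified with balanced training sets", {
  y <- factor(rep(c("a", "b", "c", "d"), times = c(40, 30, 30, 35)))
  scheme <- cvScheme(seed = 3)
  plans <- megmvpa:::makeCvPlans(y, scheme)
  expect_length(plans, 5)
  for (plan in plans) {
    kept <- plan$idx + 1L
    expect_equal(as.vector(table(y[kept])), rep(30, 4))  # undersampled
    # every kept trial in exactly one fold; per-fold class counts equal
    expect_equal(length(plan$fold), length(kept))
    tabs <- table(y[kept], plan$fold)
    expect_true(all(tabs == 6))
    # training counts identical across folds by construction
    for (f in 1:5)
      expect_equal(as.vector(rowSums(tabs[, -f, drop = FALSE])), rep(24, 4))
  }
})

test_that("the compiled CV path agrees with a manual fitGnb/predictGnb evaluation", {
  set.seed(21)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y <- factor(rep(c("a", "b", "c"), 20))
  scheme <- cvScheme(nFolds = 3, nRepeats = 2, seed = 8)
  plans <- megmvpa:::makeCvPlans(y, scheme)
  fast <- megmvpa:::.gnbCvMany(t(X), matrix(as.integer(y)), list(plans),
                               nlevels(y))
  manual <- c()
  for (plan in plans) {
    kept <- plan$idx + 1L
    for (f in sort(unique(plan$fold))) {
      tr <- kept[plan$fold != f]
      te <- kept[plan$fold == f]
      mod <- fitGnb(X[tr, , drop = FALSE], y[tr])
      pred <- predictGnb(mod, X[te, , drop = FALSE])
      manual <- c(manual, mean(pred == y[te]))
    }
  }
  expect_equal(fast[1], mean(manual), tolerance = 1e-12)
  expect_equal(crossValidate(X, y, scheme), mean(manual), tolerance = 1e-12)
})

test_that("widely separable classes decode perfectly and order does not matter", {
  set.seed(31)
  n <- 60
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * 4, sd = 0.1), n, 4)
  X[y == "b", 1] <- X[y == "b", 1] + 10
  scheme <- cvScheme(seed = 2)
  expect_equal(crossValidate(X, y, scheme), 1.0)
  # permuting rows together with their ids leaves the accuracy unchanged
  Xn <- X + rnorm(length(X))  # harder problem so accuracy is not saturated
  accRef <- crossValidate(Xn, y, scheme, trialIds = 1:n)
  perm <- sample(n)
  accPerm <- crossValidate(Xn[perm, ], y[perm], scheme, trialIds = (1:n)[perm])
  expect_equal(accPerm, accRef, tolerance = 1e-12)
})

test_that("label-independent data decode at chance on average", {
  set.seed(41)
  accs <- vapply(1:12, function(s) {
    X <- matrix(rnorm(120 * 10), 120, 10)
    y <- factor(rep(c("a", "b", "c", "d"), 30))
    crossValidate(X, y, cvScheme(seed = s))
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.25), 3 * se + 0.01)
})

test_that("insufficient class counts yield NA (non-strict) or an error", {
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- factor(c(rep("a", 9), rep("b", 3)))  # 3 < 5 folds after undersampling
  expect_error(crossValidate(X, y, cvScheme()), "fewer than nFolds")
  expect_true(is.na(crossValidate(X, y, cvScheme(), strict = FALSE)))
})

test_that("decodeMap localizes an injected effect and is structurally consistent", {
  tab <- makeStimulusTable(24, seed = 51)
  lay <- makeGridLayout(4, 4, 1)
  ef <- effectSpec("length_class", c("ch006", "ch007"), c(200, 400),
                   c(short = 0, long = 3))
  ep <- simulateEpochs(tab, lay, effects = list(ef), noiseSd = 1,
                       nSubjects = 1, nReps = 5, invalidFraction = 0.1,
                       maskFraction = 0, seed = 52)[[1]]
  tms <- c(0, 300, 700)
  map <- decodeMap(ep, "length_class", lay, searchlightSpec(150),
                   cvScheme(seed = 1), timesMs = tms)
  acc <- accuracyValues(map)
  expect_equal(dim(acc), c(16, 3))
  expect_equal(timesMs(map), tms)
  # the peak lies at the injected channels/time (or their neighborhood)
  peak <- which(acc == max(acc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  informative <- sort(unique(c(6, 7, which(neighborMatrix(lay)[6, ]),
                               which(neighborMatrix(lay)[7, ]))))
  expect_true(peak[1] %in% informative)
  expect_equal(unname(peak[2]), 2)  # 300 ms, inside the effect window
  # off-window cells hover near chance
  expect_lt(mean(acc[, c(1, 3)]), 0.58)
  # trial counts reflect the valid-trial subset
  expect_true(all(map@nTrials[map@nTrials > 0] == sum(trialInfo(ep)$valid)))
})
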