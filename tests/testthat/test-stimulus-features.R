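test_that("quantile discretization yields near-equal classes with lower-class ties", {
  expect_equal(as.vector(table(discretizeQuantiles(1:8, 4))), c(2, 2, 2, 2))
  # untied values, n = 134: sizes 33 or 34
  set.seed(1)
  sizes <- as.vector(table(discretizeQuantiles(rnorm(134), 4)))
  expect_true(all(sizes %in% c(33, 34)))
  # ties always share one label (brute force over the value's positions)
  v <- c(1, 2, 2, 2, 2, 2, 3, 4)
  lab <- discretizeQuantiles(v, 4)
  expect_equal(length(unique(lab[v == 2])), 1L)
  # tied block goes to the lower class: label of the 2s <= label of the 3
  expect_lt(as.integer(unique(lab[v == 2])), as.integer(lab[v == 3]))
  # labels ordered by value
  expect_true(all(diff(as.integer(lab[order(v)])) >= 0))
})

test_that("degenerate discretization inputs are handled", {
  expect_warning(lab <- discretizeQuantiles(rep(1, 10), 4), "identical")
  expect_equal(length(unique(lab)), 1L)
  expect_error(discretizeQuantiles(1:3, 1), ">= 2")
  expect_error(discretizeQuantiles(1:3, 4), "at least")
})

test_that("explicit-boundary binning reproduces published density groups", {
  dens <- c(0, 2, 4, 5, 7, 9, 10, 15, 19, 20, 30, 39)
  lab <- discretizeBreaks(dens, breaks = c(4, 9, 19, 39),
                          labels = c("lower", "low", "high", "higher"))
  expect_equal(as.vector(table(lab)), c(3, 3, 3, 3))
  expect_equal(as.character(lab[dens == 4]), "lower")
  expect_equal(as.character(lab[dens == 5]), "low")
  expect_error(discretizeBreaks(c(1, 50), breaks = c(4, 9, 19, 39)), "exceed")
})

test_that("contrast is zero for uniform images and positive for structure", {
  expect_equal(imageContrast(matrix(0.5, 16, 16)), 0)
  checker <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_gt(imageContrast(checker), imageContrast(matrix(1, 16, 16)))
  # shift invariance
  img <- matrix(runif(64, 0, 0.5), 8, 8)
  expect_equal(imageContrast(img + 0.3), imageContrast(img), tolerance = 1e-12)
  expect_warning(z <- imageContrast(matrix(0.2, 1, 1)), "3x3")
  expect_equal(z, 0)
  expect_error(imageContrast(matrix(2, 4, 4)), "normalized")
})

test_that("checkerboard contrast equals its closed-form local variance", {
  checker <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)
  # each 3x3 window has 4 or 5 ones -> variance p(1-p), p in {4/9, 5/9};
  # both give 20/81
  expect_equal(imageContrast(checker), 20 / 81, tolerance = 1e-12)
})

test_that("edge density matches a brute-force gradient scan on a step edge", {
  N <- 12
  img <- matrix(0, N, N)
  img[, 7:N] <- 1  # vertical step between columns 6 and 7
  # brute-force oracle: Sobel kernels applied explicitly
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  cnt <- 0
  for (i in 2:(N - 1)) for (j in 2:(N - 1)) {
    w <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (sqrt(sum(w * kx)^2 + sum(w * ky)^2) > 0.1 * 4 * sqrt(2)) cnt <- cnt + 1
  }
  expect_equal(edgeDensity(img), 100 * cnt / N^2)
  expect_gt(edgeDensity(img), 0)
})

test_that("edge density is bounded and zero for uniform images", {
  expect_equal(edgeDensity(matrix(0.3, 10, 10)), 0)
  set.seed(2)
  for (k in 1:5) {
    v <- edgeDensity(matrix(runif(100), 10, 10))
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("colorfulness follows the opponent-axis closed form", {
  gray <- array(rep(matrix(runif(64), 8, 8), 3), dim = c(8, 8, 3))
  expect_equal(colorfulness(gray), 0)
  red <- array(0, dim = c(4, 4, 3)); red[, , 1] <- 255
  expect_equal(colorfulness(red), 0.3 * sqrt(255^2 + 127.5^2), tolerance = 1e-9)
  # permutation invariance: shuffle pixel positions jointly across channels
  set.seed(3)
  img <- array(runif(4 * 4 * 3, 0, 255), dim = c(4, 4, 3))
  perm <- sample(16)
  shuf <- array(apply(img, 3, function(ch) ch[perm]), dim = c(4, 4, 3))
  expect_equal(colorfulness(shuf), colorfulness(img), tolerance = 1e-9)
  expect_error(colorfulness(matrix(0.5, 4, 4)), "3-channel")
})

test_that("attribute correlations match a hand computation on a toy table", {
  toy <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 6),
                    c = c(5, 4, 3, 2, 1))
  cm <- correlateAttributes(toy)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm["a", "c"], -1)
  # brute-force covariance / sd oracle for a-b
  n <- 5
  covAB <- sum((toy$a - mean(toy$a)) * (toy$b - mean(toy$b))) / (n - 1)
  expect_equal(cm["a", "b"], covAB / (sd(toy$a) * sd(toy$b)), tolerance = 1e-12)
  expect_identical(cm, t(cm))
  toy$d <- 1
  expect_warning(cm2 <- correlateAttributes(toy), "zero-variance")
  expect_true(is.na(cm2["a", "d"]))
})

test_that("visual features are appended with median-split bins", {
  tab <- makeStimulusTable(20, seed = 4)
  set.seed(9)
  imgs <- lapply(1:20, function(i) array(runif(8 * 8 * 3), dim = c(8, 8, 3)))
  out <- appendVisualFeatures(tab, imgs)
  expect_equal(as.vector(table(out$contrast_bin)), c(10, 10))
  expect_equal(out$colorfulness[1], colorfulness(imgs[[1]]))
})
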