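#' Discretize values into classes of approximately equal size
#'
#' Rank-based quantile binning: values are ordered and split into `nClasses`
#' groups whose sizes differ by at most one when there are no ties at bin
#' edges. Tied values always share a label and are assigned to the lower
#' class, so the labeling is a pure function of the values. Used to turn
#' phonological neighborhood density into four ordered classes
#' (smaller/small/large/larger) and visual features into two (low/high).
#'
#' @param values numeric vector, `length(values) >= nClasses`.
#' @param nClasses number of classes, >= 2.
#' @param labels optional label vector of length `nClasses`; defaults to
#'   `"q1" ... "qK"`.
#' @return ordered factor of class labels, ordered by value.
#' @examples
#' table(discretizeQuantiles(1:8, 4))       # 2,2,2,2
#' table(discretizeQuantiles(rnorm(134), 4)) # sizes 33 or 34
#' @export
discretizeQuantiles <- function(values, nClasses, labels = NULL) {
  if (nClasses < 2) abort("nClasses must be >= 2")
  n <- length(values)
  if (n < nClasses) abort("need at least nClasses values")
  if (any(!is.finite(values))) abort("values must be finite")
  if (is.null(labels)) labels <- paste0("q", seq_len(nClasses))
  if (length(labels) != nClasses) abort("labels must have length nClasses")
  if (length(unique(values)) == 1L) {
    warning("all values identical; a single class is returned")
    return(factor(rep(labels[1], n), levels = labels, ordered = TRUE))
  }
  ## min-rank keeps ties together and pushes them to the lower class
  r <- rank(values, ties.method = "min")
  cls <- ceiling(r * nClasses / n)
  factor(labels[cls], levels = labels, ordered = TRUE)
}

#' Discretize by explicit value boundaries
#'
#' Alternative to [discretizeQuantiles()] for reproducing published count
#' bins (e.g. neighborhood density groups 0-4, 5-9, 10-19, 20-39 phones,
#' which are not equal-size quantiles).
#'
#' @param values numeric vector.
#' @param breaks strictly increasing vector of class upper bounds, one per
#'   class (the last must cover the maximum value); class k holds values in
#'   `(breaks[k-1], breaks[k]]`, with the first class open below.
#' @param labels optional labels, one per class.
#' @return ordered factor.
#' @export
discretizeBreaks <- function(values, breaks, labels = NULL) {
  if (is.unsorted(breaks, strictly = TRUE)) abort("breaks must be strictly increasing")
  nClasses <- length(breaks)
  if (any(values > breaks[nClasses])) abort("values exceed the last break")
  if (is.null(labels)) labels <- paste0("b", seq_len(nClasses))
  cls <- vapply(values, function(v) which(v <= breaks)[1], integer(1))
  factor(labels[cls], levels = labels, ordered = TRUE)
}

## Grayscale conversion with standard luminance weights.
toGray <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3L && d[3] == 3L)
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  if (length(d) == 3L && d[3] == 1L) return(image[, , 1])
  abort("image must be an H x W grayscale matrix or H x W x 3 array")
}

checkIntensityRange <- function(g) {
  if (min(g) < -1e-9 || max(g) > 1 + 1e-9)
    abort("image intensities must be normalized to [0, 1]")
}

## 3x3 box sums over interior pixels of a matrix, via shifted additions.
boxSum3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  s <- matrix(0, H - 2L, W - 2L)
  for (di in 0:2) for (dj in 0:2)
    s <- s + m[di + seq_len(H - 2L), dj + seq_len(W - 2L)]
  s
}

#' Image contrast: mean local 3x3 intensity variance
#'
#' The intensity contrast between a pixel and its neighbors, quantified as
#' the variance of grayscale intensity in each full 3x3 neighborhood
#' (maximum-likelihood variance, divisor 9), averaged over all interior
#' pixels. Shift-invariant: adding a constant to all pixels leaves it
#' unchanged.
#'
#' @param image H x W grayscale matrix or H x W x 3 array, intensities in
#'   `[0, 1]`.
#' @return non-negative scalar; 0 (with a warning) for images smaller than
#'   3x3.
#' @export
imageContrast <- function(image) {
  g <- toGray(image)
  checkIntensityRange(g)
  if (nrow(g) < 3L || ncol(g) < 3L) {
    warning("image smaller than 3x3; contrast is 0")
    return(0)
  }
  m1 <- boxSum3(g) / 9
  m2 <- boxSum3(g^2) / 9
  mean(pmax(m2 - m1^2, 0))
}

## Sobel gradients on interior pixels. Returns list(gx, gy).
sobel <- function(g) {
  H <- nrow(g); W <- ncol(g)
  sub <- function(di, dj) g[di + seq_len(H - 2L), dj + seq_len(W - 2L)]
  gx <- (sub(0, 2) + 2 * sub(1, 2) + sub(2, 2)) -
        (sub(0, 0) + 2 * sub(1, 0) + sub(2, 0))
  gy <- (sub(2, 0) + 2 * sub(2, 1) + sub(2, 2)) -
        (sub(0, 0) + 2 * sub(0, 1) + sub(0, 2))
  list(gx = gx, gy = gy)
}

#' Edge density: percentage of pixels that are edge pixels
#'
#' Edges are detected with the Sobel operator on the grayscale image; a
#' pixel is an edge pixel when its gradient magnitude exceeds a fixed
#' threshold of 0.1 times the maximum possible magnitude (`4 * sqrt(2)` for
#' intensities in `[0, 1]`). The percentage is taken over all pixels of the
#' image; border pixels (no full 3x3 neighborhood) are never edge pixels.
#'
#' @inheritParams imageContrast
#' @param threshold edge threshold as a fraction of the maximum possible
#'   Sobel magnitude (default 0.1, fixed and documented for
#'   reproducibility).
#' @return percentage in `[0, 100]`.
#' @export
edgeDensity <- function(image, threshold = 0.1) {
  g <- toGray(image)
  checkIntensityRange(g)
  if (nrow(g) < 3L || ncol(g) < 3L) {
    warning("image smaller than 3x3; edge density is 0")
    return(0)
  }
  s <- sobel(g)
  mag <- sqrt(s$gx^2 + s$gy^2)
  maxMag <- 4 * sqrt(2)
  100 * sum(mag > threshold * maxMag) / (nrow(g) * ncol(g))
}

#' Colorfulness of an image
#'
#' Distributional colorfulness metric on opponent color axes
#' `rg = R - G` and `yb = (R + G) / 2 - B`:
#' \deqn{C = \sqrt{\sigma_{rg}^2 + \sigma_{yb}^2} +
#'       0.3 \sqrt{\mu_{rg}^2 + \mu_{yb}^2}}
#' This statistic correlates strongly with human colorfulness judgments.
#' Channel values are interpreted on the 0-255 scale; inputs whose maximum
#' is <= 1 are assumed normalized and are rescaled by 255. Any image with
#' `R = G = B` everywhere scores exactly 0, and the value is invariant to
#' shuffling pixel positions.
#'
#' @param image H x W x 3 array (RGB). Grayscale (single-channel) input is
#'   rejected.
#' @return non-negative scalar.
#' @export
colorfulness <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    abort("colorfulness requires a 3-channel RGB image")
  if (max(image) <= 1) image <- image * 255
  rg <- as.vector(image[, , 1] - image[, , 2])
  yb <- as.vector((image[, , 1] + image[, , 2]) / 2 - image[, , 3])
  sqrt(sd(rg)^2 + sd(yb)^2) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)
}

#' Read a stimulus image from PNG
#'
#' Thin wrapper over \pkg{png} returning an H x W x 3 array in `[0, 1]`
#' (alpha dropped, grayscale replicated to 3 channels).
#'
#' @param path path to a PNG file.
#' @return H x W x 3 numeric array.
#' @export
readStimulusImage <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    abort("package 'png' is required to read PNG images")
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Pearson correlations among numeric stimulus attributes
#'
#' @param table a stimulus table (data.frame).
#' @param vars optional character vector of columns; defaults to all numeric
#'   columns.
#' @return symmetric correlation matrix with unit diagonal; entries
#'   involving a zero-variance column are `NA` and flagged with a warning.
#' @export
correlateAttributes <- function(table, vars = NULL) {
  if (is.null(vars))
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  if (nrow(table) < 3L) abort("need at least 3 items")
  x <- as.matrix(table[, vars, drop = FALSE])
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ", paste(vars[sds == 0], collapse = ", "),
            "; correlations set to NA")
  suppressWarnings(cor(x))
}

#' Append visual features of stimulus images to a stimulus table
#'
#' Computes [imageContrast()], [edgeDensity()] and [colorfulness()] for each
#' image and appends them (plus low/high median-split bins) to the table.
#'
#' @param table stimulus table with one row per item.
#' @param images list of image arrays, one per row of `table`.
#' @return the table with columns `contrast`, `edge_density`,
#'   `colorfulness` and `contrast_bin`, `edge_density_bin`,
#'   `colorfulness_bin` replaced/added.
#' @export
appendVisualFeatures <- function(table, images) {
  if (length(images) != nrow(table))
    abort("need one image per table row")
  table$contrast <- vapply(images, imageContrast, numeric(1))
  table$edge_density <- vapply(images, edgeDensity, numeric(1))
  table$colorfulness <- vapply(images, colorfulness, numeric(1))
  for (v in c("contrast", "edge_density", "colorfulness"))
    table[[paste0(v, "_bin")]] <-
      discretizeQuantiles(table[[v]], 2L, labels = c("low", "high"))
  table
}
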