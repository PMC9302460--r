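#' Construct a regular grid sensor layout
#'
#' Builds a rectangular planar array of `nRows * nCols` channels with the
#' given spacing, standing in for a whole-head axial gradiometer array in
#' simulations. The neighbor threshold defaults to `1.2 * spacing`, which
#' on a regular grid yields the 4-connected (rook) neighborhood: axial
#' neighbors at Euclidean distance `spacing` qualify, diagonal ones at
#' `sqrt(2) * spacing ~ 1.41 * spacing` do not. A corner channel then has
#' 2 neighbors and an interior channel 4; widen the threshold beyond
#' `sqrt(2) * spacing` for an 8-neighborhood.
#'
#' @param nRows,nCols grid dimensions, each >= 1.
#' @param spacing distance between adjacent channels (arbitrary planar units).
#' @param neighborThreshold distance below which channels are neighbors;
#'   default `1.2 * spacing`.
#' @return a [SensorLayout-class].
#' @examples
#' lay <- makeGridLayout(3, 3, 1)
#' rowSums(neighborMatrix(lay))  # corner channels have 2 neighbors, center 4
#' @export
makeGridLayout <- function(nRows, nCols, spacing = 1,
                           neighborThreshold = 1.2 * spacing) {
  if (length(nRows) != 1L || length(nCols) != 1L ||
      nRows < 1 || nCols < 1 || nRows != round(nRows) || nCols != round(nCols))
    abort("nRows and nCols must be positive integers")
  assertScalarNumber(spacing, "spacing", positive = TRUE)
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  idx <- expand.grid(col = seq_len(nCols), row = seq_len(nRows))
  pos <- cbind(x = (idx$col - 1) * spacing, y = (idx$row - 1) * spacing)
  ids <- sprintf("ch%03d", seq_len(nRows * nCols))
  new("SensorLayout", channelIds = ids, positions = pos,
      neighborThreshold = neighborThreshold)
}

#' Neighbor adjacency of a sensor layout
#'
#' Channels are first-order neighbors when their planar distance is strictly
#' below the layout's threshold. The relation is symmetric and irreflexive
#' by construction; the same adjacency drives the planar gradient estimate,
#' the searchlight channel sets, and the spatial part of cluster formation.
#'
#' @param layout a [SensorLayout-class].
#' @return logical adjacency matrix (channels x channels) with dimnames.
#' @export
neighborMatrix <- function(layout) {
  stopifnot(is(layout, "SensorLayout"))
  d <- as.matrix(stats::dist(layout@positions))
  adj <- d < layout@neighborThreshold
  diag(adj) <- FALSE
  dimnames(adj) <- list(layout@channelIds, layout@channelIds)
  adj
}

#' Neighbor graph with degree statistics
#'
#' Convenience wrapper around [neighborMatrix()] that also reports per-channel
#' degrees, for checking the array against expectations such as a mean
#' neighbor count around 7-8 with range 4-10 on a real 275-channel helmet.
#' A channel with no neighbors triggers a warning (it cannot support a planar
#' gradient estimate and its searchlight degenerates).
#'
#' @param layout a [SensorLayout-class].
#' @return list with `adjacency` (logical matrix), `degree` (named integer
#'   vector) and `stats` (mean, sd, min, max of degree).
#' @export
neighborGraph <- function(layout) {
  adj <- neighborMatrix(layout)
  deg <- rowSums(adj)
  if (any(deg == 0))
    warning("layout has ", sum(deg == 0), " channel(s) with no neighbors")
  list(
    adjacency = adj,
    degree = stats::setNames(as.integer(deg), layout@channelIds),
    stats = c(mean = mean(deg), sd = stats::sd(deg),
              min = min(deg), max = max(deg))
  )
}

## Degree summary without the zero-degree warning (used by show()).
degreeStats <- function(layout) {
  deg <- rowSums(neighborMatrix(layout))
  c(mean = mean(deg), sd = if (length(deg) > 1) stats::sd(deg) else 0,
    min = min(deg), max = max(deg))
}

## Neighbor index list (row indices per channel), optionally with the
## channel itself included; used by searchlight and planar code.
neighborIndexList <- function(layout, includeSelf = FALSE) {
  adj <- neighborMatrix(layout)
  lapply(seq_len(nrow(adj)), function(i) {
    nb <- which(adj[i, ])
    if (includeSelf) sort(c(i, nb)) else nb
  })
}

#' Export the neighbor relation as an edge list
#'
#' @param layout a [SensorLayout-class].
#' @param file optional path; when given, written as a two-column TSV.
#' @return data.frame with columns `from`, `to` (each undirected edge once).
#' @export
neighborEdgeList <- function(layout, file = NULL) {
  adj <- neighborMatrix(layout)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = layout@channelIds[idx[, 1]],
                      to = layout@channelIds[idx[, 2]],
                      stringsAsFactors = FALSE)
  if (!is.null(file))
    write.table(edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
  edges
}
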