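.centralityScores <- function(measure, window, scores) {
  new("CentralityScores", measure = measure, window = as.integer(window),
      scores = scores)
}

#' Temporal in-closeness centrality
#'
#' The temporal in-component of a node v is the set of nodes with a
#' spatio-temporal path to v (plus v itself). The in-farness of v is the
#' mean temporal distance from those nodes to v; temporal in-closeness is
#' its reciprocal. A node whose in-component is just itself has infinite
#' in-farness and closeness 0. Scores are in reciprocal seconds.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param window integer (start, end) snapshot window (default full).
#' @param ap optional precomputed \code{\link{allPairs}} result.
#' @return A \linkS4class{CentralityScores} (measure "TC").
#' @export
temporalInCloseness <- function(net, window = NULL, ap = NULL) {
  window <- .checkWindow(net, window)
  if (is.null(ap)) ap <- allPairs(net, window)
  lat <- ap$latency
  scores <- vapply(seq_len(nNodes(net)), function(v) {
    inLat <- lat[-v, v]
    inLat <- inLat[is.finite(inLat)]
    if (length(inLat) == 0) return(0)
    1 / mean(inLat)
  }, numeric(1))
  names(scores) <- net@nodes
  .centralityScores("TC", window, scores)
}

.betweennessPair <- function(net, window, infSpeeds = FALSE,
                             spatialTiebreak = TRUE) {
  ap <- allPairs(net, window, centrality = TRUE, infSpeeds = infSpeeds,
                 spatialTiebreak = spatialTiebreak)
  list(pb = ap$pb, be = ap$be)
}

#' Path betweenness centrality
#'
#' For each ordered pair (w, u), the fraction of spatio-temporally shortest
#' paths from w to u that pass through v as an interior node, summed over
#' all pairs (Brandes-style accumulation on each origin's shortest-path
#' DAG). Endpoints are excluded from their own paths' interiors.
#'
#' @inheritParams temporalInCloseness
#' @return A \linkS4class{CentralityScores} (measure "PB").
#' @export
pathBetweenness <- function(net, window = NULL) {
  window <- .checkWindow(net, window)
  .centralityScores("PB", window, .betweennessPair(net, window)$pb)
}

#' Betweenness efficiency centrality
#'
#' Sums, over all source-destination pairs that have at least one
#' spatio-temporally shortest path through v (each pair counted once), the
#' reciprocal temporal distance of the pair in timestep units. High scores
#' mark bottlenecks carrying temporally efficient flows.
#'
#' @inheritParams temporalInCloseness
#' @return A \linkS4class{CentralityScores} (measure "BE").
#' @export
betweennessEfficiency <- function(net, window = NULL) {
  window <- .checkWindow(net, window)
  .centralityScores("BE", window, .betweennessPair(net, window)$be)
}

#' Pure-temporal path betweenness centrality
#'
#' Path betweenness computed on the derived network in which every existing
#' edge has infinite propagation speed: paths are constrained only by edge
#' presence and time-ordering, shortest paths are minimum-latency only, and
#' all minimum-latency paths are counted (no spatial tie-break).
#'
#' @inheritParams temporalInCloseness
#' @return A \linkS4class{CentralityScores} (measure "PTPB").
#' @export
pureTemporalPathBetweenness <- function(net, window = NULL) {
  window <- .checkWindow(net, window)
  pb <- .betweennessPair(net, window, infSpeeds = TRUE,
                         spatialTiebreak = FALSE)$pb
  .centralityScores("PTPB", window, pb)
}

#' Degree centrality on the static aggregate
#'
#' In- or out-degree of each node in the unweighted static aggregate graph
#' (an edge is present iff it appears in at least one snapshot).
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param direction "in" or "out".
#' @return A \linkS4class{CentralityScores} (measure "ID" or "OD").
#' @export
degreeScores <- function(net, direction = c("in", "out")) {
  direction <- match.arg(direction)
  g <- aggregateGraph(net)
  deg <- igraph::degree(g, mode = direction)
  scores <- as.numeric(deg)
  names(scores) <- net@nodes
  .centralityScores(if (direction == "in") "ID" else "OD",
                    c(1L, nSnapshots(net)), scores)
}
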