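#' Create an observation window
#'
#' @param nSteps number of snapshots \code{T} (positive integer).
#' @param tau snapshot duration in seconds.
#' @param t1 start time in seconds (default 0).
#' @return An \linkS4class{ObservationWindow}.
#' @export
observationWindow <- function(nSteps, tau, t1 = 0) {
  new("ObservationWindow", t1 = as.numeric(t1), nSteps = as.integer(nSteps),
      tau = as.numeric(tau))
}

#' Create a metric space
#'
#' @param kind "euclidean" or "geodesic" (WGS-84 ellipsoid; coordinates are
#'   latitude, longitude in decimal degrees).
#' @param dimension coordinate dimension (euclidean only; geodesic is 2).
#' @param units length unit, "m" or "km"; speeds are units per second.
#' @return A \linkS4class{MetricSpace}.
#' @export
metricSpace <- function(kind = c("euclidean", "geodesic"), dimension = 2,
                        units = "m") {
  kind <- match.arg(kind)
  new("MetricSpace", kind = kind, dimension = as.integer(dimension),
      units = units)
}

.emptySnapshot <- function(n) {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(n, n))
}

.snapshotsFromEdges <- function(edges, nodes, nSteps) {
  n <- length(nodes)
  snaps <- lapply(seq_len(nSteps), function(i) .emptySnapshot(n))
  if (is.null(edges) || nrow(edges) == 0) return(snaps)
  t <- as.integer(edges$t)
  if (any(is.na(t)) || any(t < 1L) || any(t > nSteps))
    stop("edge timestep outside 1..T")
  si <- match(as.character(edges$source), nodes)
  ti <- match(as.character(edges$target), nodes)
  if (anyNA(si) || anyNA(ti)) stop("unknown node id in edge table")
  if (any(si == ti)) stop("self-edges are not allowed")
  sp <- edges$speed
  if (is.character(sp)) sp <- ifelse(tolower(trimws(sp)) == "inf", Inf,
                                     suppressWarnings(as.numeric(sp)))
  sp <- as.numeric(sp)
  if (anyNA(sp)) stop("unparseable speed value")
  if (any(sp <= 0))
    stop("edge speeds must be strictly positive (use 'inf' for instantaneous)")
  if (anyDuplicated(cbind(t, si, ti)))
    stop("duplicate directed edge within a snapshot")
  for (i in unique(t)) {
    k <- which(t == i)
    snaps[[i]] <- Matrix::sparseMatrix(i = si[k], j = ti[k], x = sp[k],
                                       dims = c(n, n))
  }
  snaps
}

#' Construct a spatio-temporal network
#'
#' @param nodes character vector of node identifiers.
#' @param positions either an N x k coordinate matrix (static positions) or
#'   an N x k x T array of per-snapshot trajectories. Row order follows
#'   \code{nodes}.
#' @param edges a data.frame with columns \code{t, source, target, speed}
#'   (\code{t} in 1..T; speed in length units per second, \code{Inf} or the
#'   string "inf" for instantaneous), or a pre-built list of T sparse N x N
#'   speed matrices.
#' @param window an \linkS4class{ObservationWindow}.
#' @param metric a \linkS4class{MetricSpace} (default 2-D Euclidean, metres).
#' @return A validated \linkS4class{SpatioTemporalNetwork}.
#' @export
stn <- function(nodes, positions, edges, window, metric = metricSpace()) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  Tn <- window@nSteps
  if (is.matrix(positions)) {
    staticPos <- TRUE
    pos <- array(positions, dim = c(n, ncol(positions), Tn))
  } else if (is.array(positions) && length(dim(positions)) == 3L) {
    pos <- positions
    staticPos <- all(apply(pos, c(1, 2), function(x) all(x == x[1])))
  } else stop("positions must be an N x k matrix or N x k x T array")
  if (is.data.frame(edges)) {
    snaps <- .snapshotsFromEdges(edges, nodes, Tn)
  } else if (is.list(edges)) {
    snaps <- lapply(edges, methods::as, "CsparseMatrix")
  } else stop("edges must be a data.frame or list of sparse matrices")
  net <- new("SpatioTemporalNetwork", nodes = nodes, positions = pos,
             staticPositions = staticPos, metric = metric, snapshots = snaps,
             window = window, cache = new.env(parent = emptyenv()))
  methods::validObject(net)
  net
}

# ---- accessors ---------------------------------------------------------

#' @rdname stn
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @export
nodeIds <- function(net) net@nodes

#' @rdname stn
#' @export
nNodes <- function(net) length(net@nodes)

#' @rdname stn
#' @export
nSnapshots <- function(net) net@window@nSteps

#' @rdname stn
#' @export
obsWindow <- function(net) net@window

#' @rdname stn
#' @export
metricSpaceOf <- function(net) net@metric

#' Speed matrix of one snapshot
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param i snapshot index in 1..T.
#' @return Sparse N x N matrix of propagation speeds (0 = no edge).
#' @export
snapshotSpeeds <- function(net, i) {
  stopifnot(i >= 1, i <= nSnapshots(net))
  net@snapshots[[i]]
}

#' Node coordinates at one snapshot
#' @inheritParams snapshotSpeeds
#' @return N x k coordinate matrix.
#' @export
nodePositions <- function(net, i = 1L) {
  stopifnot(i >= 1, i <= nSnapshots(net))
  p <- net@positions[, , i, drop = FALSE]
  dim(p) <- dim(net@positions)[1:2]
  rownames(p) <- net@nodes
  p
}

#' Long-format edge table of a network
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @return data.frame with columns t, source, target, speed.
#' @export
edgeTable <- function(net) {
  rows <- lapply(seq_len(nSnapshots(net)), function(i) {
    S <- methods::as(net@snapshots[[i]], "TsparseMatrix")
    if (length(S@x) == 0) return(NULL)
    data.frame(t = i, source = net@nodes[S@i + 1L],
               target = net@nodes[S@j + 1L], speed = S@x,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(t = integer(0), source = character(0),
                      target = character(0), speed = numeric(0))
  out[order(out$t, out$source, out$target), , drop = FALSE]
}

# ---- distances ---------------------------------------------------------

.pairwiseDist <- function(coords, metric) {
  n <- nrow(coords)
  if (metric@kind == "euclidean") {
    D <- as.matrix(stats::dist(coords))
  } else {
    # geodesic on WGS-84; coords are (lat, lon), geosphere wants (lon, lat)
    ll <- cbind(coords[, 2], coords[, 1])
    D <- matrix(0, n, n)
    for (v in seq_len(n - 1)) {
      w <- (v + 1):n
      d <- geosphere::distVincentyEllipsoid(ll[v, , drop = FALSE],
                                            ll[w, , drop = FALSE])
      D[v, w] <- d
      D[w, v] <- d
    }
    if (metric@units == "km") D <- D / 1000
  }
  dimnames(D) <- NULL
  D
}

#' Pairwise physical distance matrix at a snapshot
#'
#' Distances between all node pairs at snapshot \code{i}, in the metric
#' space's length units. For static positions the matrix is computed once
#' and cached.
#'
#' @inheritParams snapshotSpeeds
#' @return Dense N x N symmetric matrix with zero diagonal.
#' @export
distanceMatrix <- function(net, i = 1L) {
  stopifnot(i >= 1, i <= nSnapshots(net))
  key <- if (net@staticPositions) "static" else paste0("t", i)
  if (!is.null(net@cache[[key]])) return(net@cache[[key]])
  D <- .pairwiseDist(nodePositions(net, i), net@metric)
  net@cache[[key]] <- D
  D
}

# ---- aggregate view ----------------------------------------------------

#' Unweighted static aggregate of a spatio-temporal network
#'
#' A directed edge (v, w) is present in the aggregate iff it appears in at
#' least one snapshot. The returned igraph carries graph attributes
#' \code{nEdges} (|E*|) and \code{density} (|E*| / (N(N-1))).
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @return A directed \code{igraph} graph.
#' @export
aggregateGraph <- function(net) {
  n <- nNodes(net)
  agg <- Reduce(`+`, lapply(net@snapshots, function(S) (S != 0) * 1))
  adj <- as.matrix(agg != 0) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::V(g)$name <- net@nodes
  ne <- sum(adj)
  g <- igraph::set_graph_attr(g, "nEdges", ne)
  igraph::set_graph_attr(g, "density", ne / (n * (n - 1)))
}

# ---- validation --------------------------------------------------------

#' Validate a spatio-temporal network
#'
#' Checks the modelling assumptions: no two nodes may occupy the same
#' coordinate in any snapshot (error), and the minimum direct propagation
#' duration min(D/S) over all snapshot edges with finite speed should not be
#' smaller than the granularity tau, otherwise the discrete representation
#' under-samples the system's dynamics (warning).
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @return A \linkS4class{ValidationReport}.
#' @export
validateNetwork <- function(net) {
  findings <- list()
  add <- function(severity, code, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      stringsAsFactors = FALSE)
  steps <- if (net@staticPositions) 1L else seq_len(nSnapshots(net))
  for (i in steps) {
    co <- nodePositions(net, i)
    dup <- duplicated(co) | duplicated(co, fromLast = TRUE)
    if (any(dup))
      add("error", "colocated_nodes",
          sprintf("nodes %s share a coordinate in snapshot %d",
                  paste(net@nodes[dup], collapse = ", "), i))
  }
  minDur <- Inf
  for (i in seq_len(nSnapshots(net))) {
    S <- methods::as(net@snapshots[[i]], "TsparseMatrix")
    fin <- is.finite(S@x) & S@x > 0
    if (!any(fin)) next
    D <- distanceMatrix(net, i)
    d <- D[cbind(S@i[fin] + 1L, S@j[fin] + 1L)]
    minDur <- min(minDur, d / S@x[fin])
  }
  if (is.finite(minDur) && minDur < net@window@tau)
    add("warning", "undersampled",
        sprintf(paste0("minimum direct propagation duration %.6g s is ",
                       "smaller than tau = %.6g s; the representation ",
                       "under-samples the temporal dynamics (bound sometimes ",
                       "printed as a distance-speed product; the duration ",
                       "form D/S is used here)"),
                minDur, net@window@tau))
  df <- if (length(findings)) do.call(rbind, findings) else
    data.frame(severity = character(0), code = character(0),
               message = character(0), stringsAsFactors = FALSE)
  new("ValidationReport", findings = df,
      pass = !any(df$severity == "error"))
}

# ---- file formats ------------------------------------------------------

#' Write a network to plain-text files
#'
#' Writes \code{nodes.csv} (static positions) or \code{trajectory.csv}
#' (time-varying positions), \code{edges.csv} (\code{t,source,target,speed};
#' infinite speeds serialised as "inf") and \code{meta.json}
#' (\code{tau, T, t1, metric}) into \code{dir}.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
saveNetwork <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  k <- net@metric@dimension
  coordNames <- c("x", "y", "z")[seq_len(k)]
  if (net@staticPositions) {
    co <- nodePositions(net, 1L)
    df <- data.frame(node_id = net@nodes, co, stringsAsFactors = FALSE)
    names(df) <- c("node_id", coordNames)
    utils::write.csv(df, file.path(dir, "nodes.csv"), row.names = FALSE)
  } else {
    rows <- lapply(seq_len(nSnapshots(net)), function(i) {
      co <- nodePositions(net, i)
      df <- data.frame(t = i, node_id = net@nodes, co,
                       stringsAsFactors = FALSE)
      names(df) <- c("t", "node_id", coordNames)
      df
    })
    utils::write.csv(do.call(rbind, rows), file.path(dir, "trajectory.csv"),
                     row.names = FALSE)
  }
  ed <- edgeTable(net)
  ed$speed <- ifelse(is.infinite(ed$speed), "inf",
                     format(ed$speed, digits = 17, scientific = FALSE,
                            trim = TRUE))
  utils::write.csv(ed, file.path(dir, "edges.csv"), row.names = FALSE)
  meta <- list(tau = net@window@tau, T = nSnapshots(net), t1 = net@window@t1,
               metric = list(kind = net@metric@kind,
                             dimension = net@metric@dimension,
                             units = net@metric@units))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a network from plain-text files
#'
#' @param nodesFile CSV with columns \code{node_id,x,y[,z]} (static) or
#'   \code{t,node_id,x,y[,z]} (trajectories; missing (node, t) rows inherit
#'   the node's most recent position).
#' @param edgesFile CSV with columns \code{t,source,target,speed}; speed in
#'   length units per second or the literal "inf".
#' @param metaFile JSON with fields \code{tau, T, t1, metric}.
#' @param bidirectional when TRUE each undirected source record expands to
#'   two directed edges.
#' @return A validated \linkS4class{SpatioTemporalNetwork}; loading fails if
#'   validation reports an error.
#' @export
loadNetwork <- function(nodesFile, edgesFile, metaFile,
                        bidirectional = FALSE) {
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  window <- observationWindow(meta$T, meta$tau,
                              if (is.null(meta$t1)) 0 else meta$t1)
  metric <- metricSpace(meta$metric$kind,
                        if (is.null(meta$metric$dimension)) 2 else
                          meta$metric$dimension,
                        meta$metric$units)
  ntab <- utils::read.csv(nodesFile, stringsAsFactors = FALSE)
  k <- metric@dimension
  coordNames <- c("x", "y", "z")[seq_len(k)]
  if (metric@kind == "geodesic" && all(c("lat", "lon") %in% names(ntab))) {
    ntab$x <- ntab$lat; ntab$y <- ntab$lon
  }
  if ("t" %in% names(ntab)) {
    nodes <- sort(unique(as.character(ntab$node_id)))
    Tn <- window@nSteps
    pos <- array(NA_real_, dim = c(length(nodes), k, Tn))
    ntab <- ntab[order(ntab$t), , drop = FALSE]
    for (r in seq_len(nrow(ntab))) {
      v <- match(as.character(ntab$node_id[r]), nodes)
      ti <- as.integer(ntab$t[r])
      if (is.na(ti) || ti < 1L || ti > Tn) stop("trajectory timestep outside 1..T")
      pos[v, , ti] <- as.numeric(ntab[r, coordNames])
    }
    # last observation carried forward; a node with no position is an error
    for (v in seq_along(nodes)) {
      if (all(is.na(pos[v, 1, ]))) stop(sprintf("node %s has no position", nodes[v]))
      first <- which(!is.na(pos[v, 1, ]))[1]
      pos[v, , seq_len(first)] <- pos[v, , first]
      for (ti in seq_len(Tn)[-1])
        if (is.na(pos[v, 1, ti])) pos[v, , ti] <- pos[v, , ti - 1L]
    }
    positions <- pos
  } else {
    nodes <- as.character(ntab$node_id)
    positions <- as.matrix(ntab[, coordNames, drop = FALSE])
    if (anyNA(positions)) stop("missing coordinates in nodes table")
  }
  ed <- utils::read.csv(edgesFile, stringsAsFactors = FALSE,
                        colClasses = c(speed = "character"))
  if (bidirectional && nrow(ed)) {
    rev <- ed; rev$source <- ed$target; rev$target <- ed$source
    ed <- unique(rbind(ed, rev))
  }
  net <- stn(nodes, positions, ed, window, metric)
  rep <- validateNetwork(net)
  if (!rep@pass)
    stop("network failed validation: ",
         paste(rep@findings$message[rep@findings$severity == "error"],
               collapse = "; "))
  net
}

# ---- show methods ------------------------------------------------------

setMethod("show", "SpatioTemporalNetwork", function(object) {
  ne <- sum(vapply(object@snapshots, function(S) length(S@x), numeric(1)))
  cat(sprintf(paste0("SpatioTemporalNetwork: %d nodes, %d snapshots ",
                     "(tau = %g s), %d edge records\n"),
              nNodes(object), nSnapshots(object), object@window@tau, ne))
  cat(sprintf("  metric: %s (%s), positions %s\n", object@metric@kind,
              object@metric@units,
              if (object@staticPositions) "static" else "time-varying"))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s (%d finding(s))\n",
              if (object@pass) "PASS" else "FAIL", nrow(object@findings)))
  if (nrow(object@findings))
    for (r in seq_len(nrow(object@findings)))
      cat(sprintf("  [%s] %s: %s\n", object@findings$severity[r],
                  object@findings$code[r], object@findings$message[r]))
})

setMethod("show", "CentralityScores", function(object) {
  cat(sprintf("CentralityScores (%s), window %d..%d\n", object@measure,
              object@window[1], object@window[2]))
  print(utils::head(sort(object@scores, decreasing = TRUE), 10))
})

setMethod("show", "RobustnessCurve", function(object) {
  cat(sprintf("RobustnessCurve (%s): %d fractions, %d realization(s)\n",
              object@strategy, length(object@fractions),
              object@realizations))
})
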