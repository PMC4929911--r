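# Dense per-step engine inputs for a snapshot window.
# infSpeeds = TRUE replaces every existing edge's speed by +Inf (the derived
# network used by pure-temporal path analysis).
.engineInputs <- function(net, window, infSpeeds = FALSE) {
  a <- window[1]; b <- window[2]
  stopifnot(a >= 1, b <= nSnapshots(net), a <= b)
  speeds <- lapply(a:b, function(i) {
    m <- as.matrix(net@snapshots[[i]])
    if (infSpeeds) m[m > 0] <- Inf
    m
  })
  dists <- if (net@staticPositions) list(distanceMatrix(net, 1L)) else
    lapply(a:b, function(i) distanceMatrix(net, i))
  list(speeds = speeds, dists = dists, tau = net@window@tau)
}

.checkWindow <- function(net, window) {
  if (is.null(window)) window <- c(1L, nSnapshots(net))
  window <- as.integer(window)
  stopifnot(length(window) == 2, window[1] >= 1,
            window[2] <= nSnapshots(net), window[1] <= window[2])
  window
}

#' Initialise the constrained-propagation process
#'
#' Sets up the state at the window's first snapshot: the reachability set is
#' the origin alone and the progress matrix is all zero.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param origin origin node id.
#' @param start snapshot index at which propagation begins.
#' @return A \linkS4class{PropagationState}.
#' @export
initPropagation <- function(net, origin, start = 1L) {
  v0 <- match(origin, net@nodes)
  if (is.na(v0)) stop("unknown origin node: ", origin)
  n <- nNodes(net)
  arrival <- rep(NA_integer_, n)
  arrival[v0] <- as.integer(start)
  new("PropagationState", origin = origin, nodes = net@nodes,
      windowStart = as.integer(start), step = as.integer(start),
      arrival = arrival,
      P = matrix(0, n, n, dimnames = list(net@nodes, net@nodes)),
      preds = rep(list(data.frame(pred = integer(0), step = integer(0),
                                  hop = numeric(0))), n))
}

#' Advance the propagation process by one timestep
#'
#' Applies the progress-matrix update rule for snapshot \code{i}: for each
#' reached node v and unreached node w joined by an edge in snapshot i, the
#' progress P[v, w] grows by min(tau * S[v, w], remaining distance), where
#' the remaining distance is max(0, D[v, w] - P[v, w]); if the edge is
#' absent, progress resets to zero. Nodes whose accumulated progress meets
#' their current physical distance from any reached node join the
#' reachability set, recording every such predecessor.
#'
#' @param state a \linkS4class{PropagationState} at step \code{i - 1}.
#' @param net the network the state belongs to.
#' @param i snapshot index to apply (\code{i >= 2}).
#' @return The advanced \linkS4class{PropagationState}.
#' @export
propagationStep <- function(state, net, i) {
  i <- as.integer(i)
  if (i != state@step + 1L) stop("state holds step ", state@step,
                                 "; expected i = ", state@step + 1L)
  if (i < 2L || i > nSnapshots(net)) stop("timestep out of range")
  if (!identical(state@nodes, net@nodes)) stop("state/network node-set mismatch")
  n <- nNodes(net)
  S <- as.matrix(net@snapshots[[i]])
  D <- distanceMatrix(net, i)
  tau <- net@window@tau
  reached <- !is.na(state@arrival)
  P <- state@P
  act <- outer(reached, !reached)       # reached v -> unreached w
  diag(act) <- FALSE
  hasEdge <- S > 0
  upd <- act & hasEdge
  q <- pmax(0, D[upd] - P[upd])
  P[upd] <- P[upd] + pmin(tau * S[upd], q)
  P[act & !hasEdge] <- 0                # edge vanished: progress lost
  arrived <- act & (P >= D - 1e-9 * pmax(1, D))
  newly <- which(!reached & apply(arrived, 2, any))
  arrival <- state@arrival
  preds <- state@preds
  for (w in newly) {
    arrival[w] <- i
    vs <- which(arrived[, w])
    preds[[w]] <- data.frame(pred = vs, step = i, hop = P[vs, w])
  }
  methods::initialize(state, step = i, arrival = arrival, P = P,
                      preds = preds)
}

.summaryFromEngine <- function(res, net, window, origin) {
  tau <- net@window@tau
  arrivalOff <- res$arrival
  lat <- ifelse(is.na(arrivalOff), Inf, arrivalOff * tau)
  arrivalIdx <- ifelse(is.na(arrivalOff), NA_integer_,
                       as.integer(arrivalOff + window[1]))
  sdist <- res$sdist
  sigma <- res$sigma
  names(lat) <- names(sdist) <- names(arrivalIdx) <- names(sigma) <-
    net@nodes
  new("ShortestPathSummary", origin = origin, nodes = net@nodes,
      window = window, arrival = arrivalIdx, latency = lat, sdist = sdist,
      sigma = sigma, dag = res$dag, hops = res$hops)
}

#' Run constrained propagation from one origin
#'
#' Iterates the propagation process over a snapshot window and summarises
#' the spatio-temporal shortest paths it induces: per destination, the
#' minimum latency, the minimum spatial length among minimum-latency
#' arrivals, the number of spatio-temporally shortest paths, and the
#' predecessor DAG restricted to those paths. Latency counts from the window
#' start (waiting at the origin is included).
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param origin origin node id.
#' @param window integer (start, end) snapshot indices; default the full
#'   observation window.
#' @param trace when TRUE, also return the per-step reachability sets and
#'   progress matrices.
#' @param spatialTiebreak when FALSE, all minimum-latency predecessors are
#'   kept in the DAG (no spatial tie-break); used for pure-temporal path
#'   counting.
#' @return A \linkS4class{ShortestPathSummary}, or when \code{trace = TRUE}
#'   a list with elements \code{summary} and \code{trace} (a list of
#'   \linkS4class{PropagationState}, one per window step).
#' @export
runPropagation <- function(net, origin, window = NULL, trace = FALSE,
                           spatialTiebreak = TRUE) {
  window <- .checkWindow(net, window)
  v0 <- match(origin, net@nodes)
  if (is.na(v0)) stop("unknown origin node: ", origin)
  inp <- .engineInputs(net, window)
  res <- cpp_propagate(inp$speeds, inp$dists, inp$tau, v0 - 1L,
                       spatialTiebreak, trace, FALSE)
  summ <- .summaryFromEngine(res, net, window, origin)
  if (!trace) return(summ)
  states <- lapply(seq_along(res$traceK), function(s) {
    stepIdx <- as.integer(window[1] + s - 1L)
    arrivalIdx <- unname(summ@arrival)
    arrivalIdx[!is.na(arrivalIdx) & arrivalIdx > stepIdx] <- NA_integer_
    preds <- lapply(seq_len(nNodes(net)), function(w) {
      if (is.na(arrivalIdx[w]) || arrivalIdx[w] == window[1] ||
          arrivalIdx[w] > stepIdx)
        return(data.frame(pred = integer(0), step = integer(0),
                          hop = numeric(0)))
      data.frame(pred = res$predsAll[[w]], step = arrivalIdx[w],
                 hop = res$hopsAll[[w]])
    })
    P <- res$traceP[[s]]
    dimnames(P) <- list(net@nodes, net@nodes)
    new("PropagationState", origin = origin, nodes = net@nodes,
        windowStart = window[1], step = stepIdx,
        arrival = arrivalIdx, P = P, preds = preds)
  })
  list(summary = summ, trace = states)
}

#' All-pairs spatio-temporal distances and reachability
#'
#' Runs the propagation process from every origin over the same window.
#' Origins are independent, so results do not depend on execution order.
#'
#' @inheritParams runPropagation
#' @param centrality when TRUE, additionally accumulate per-origin
#'   path-betweenness and betweenness-efficiency contributions.
#' @param infSpeeds when TRUE, analyse the derived network in which every
#'   edge has infinite speed (pure-temporal paths).
#' @param jobs number of worker processes for the per-origin sweep
#'   (forked via the parallel package; origins share no mutable state, so
#'   results are identical to the serial run).
#' @return A list with N x N matrices \code{latency} (seconds),
#'   \code{latSteps} (timestep units), \code{sdist} (length units),
#'   \code{sigma} (shortest-path counts), logical \code{reach} (TRUE on the
#'   diagonal), and when requested numeric vectors \code{pb}, \code{be}.
#'   Rows index origins.
#' @export
allPairs <- function(net, window = NULL, centrality = FALSE,
                     infSpeeds = FALSE, spatialTiebreak = TRUE, jobs = 1L) {
  window <- .checkWindow(net, window)
  inp <- .engineInputs(net, window, infSpeeds = infSpeeds)
  n <- nNodes(net)
  latSteps <- matrix(Inf, n, n, dimnames = list(net@nodes, net@nodes))
  sdist <- latSteps
  sigma <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
  pb <- be <- stats::setNames(numeric(n), net@nodes)
  one <- function(v) cpp_propagate(inp$speeds, inp$dists, inp$tau, v - 1L,
                                   spatialTiebreak, FALSE, centrality)
  perOrigin <- if (jobs > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(seq_len(n), one, mc.cores = jobs)
  else lapply(seq_len(n), one)
  for (v in seq_len(n)) {
    res <- perOrigin[[v]]
    latSteps[v, ] <- ifelse(is.na(res$arrival), Inf, res$arrival)
    sdist[v, ] <- res$sdist
    sigma[v, ] <- res$sigma
    if (centrality) {
      pb <- pb + res$pb
      be <- be + res$be
    }
  }
  out <- list(latency = latSteps * net@window@tau, latSteps = latSteps,
              sdist = sdist, sigma = sigma, reach = is.finite(latSteps),
              window = window, tau = net@window@tau)
  if (centrality) {
    out$pb <- pb
    out$be <- be
  }
  out
}

#' Giant-component growth with the temporal horizon
#'
#' For each horizon h, restricts the observation window to its first
#' floor(h / tau) snapshots and computes the giant strong component size S
#' of the induced reachability digraph. S is non-decreasing in h.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param horizons numeric vector of horizon durations in seconds (each in
#'   (0, T * tau]).
#' @return data.frame with columns \code{h}, \code{steps}, \code{S}.
#' @export
horizonGrowth <- function(net, horizons) {
  if (length(horizons) == 0) stop("empty horizon list")
  tau <- net@window@tau
  Tn <- nSnapshots(net)
  if (any(horizons <= 0) || any(horizons > Tn * tau + 1e-9))
    stop("horizons must lie in (0, T * tau]")
  S <- vapply(horizons, function(h) {
    steps <- max(1L, min(Tn, as.integer(floor(h / tau + 1e-9))))
    ap <- allPairs(net, c(1L, steps))
    .giantStrongSize(ap)
  }, numeric(1))
  data.frame(h = horizons, steps = pmax(1L, pmin(Tn, floor(horizons / tau + 1e-9))),
             S = S)
}
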