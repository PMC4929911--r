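# Run expr under a local seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Two-city worked example
#'
#' Two nodes 150 km apart (Euclidean plane, km units) joined by a
#' persistent directed edge of speed 200 km/h, observed over six 15-minute
#' snapshots. One propagation step accumulates 50 km of progress, so three
#' timesteps must elapse before the second city is reached.
#'
#' @return A \linkS4class{SpatioTemporalNetwork}.
#' @export
twoCityFixture <- function() {
  nodes <- c("v", "w")
  pos <- rbind(c(0, 0), c(150, 0))
  edges <- data.frame(t = 1:6, source = "v", target = "w",
                      speed = 200 / 3600)  # 200 km/h in km/s
  stn(nodes, pos, edges, observationWindow(6, 900),
      metricSpace("euclidean", 2, "km"))
}

#' Five-node worked example with partial progress and resets
#'
#' Five nodes A-E at integer coordinates on the Euclidean plane, tau = 1 s,
#' all speeds 1 m/s, six snapshots. Propagating from A at t1: B arrives at
#' t2; C shows partial progress at t3 and arrives at t4; propagation toward
#' D resets when its edge disappears at t3, restarts at t4 and fails again
#' at t6; E is reached via B and C with latency 5 s and spatial path length
#' 4 m.
#'
#' @return A \linkS4class{SpatioTemporalNetwork}.
#' @export
fiveNodeFixture <- function() {
  nodes <- c("A", "B", "C", "D", "E")
  pos <- rbind(A = c(0, 0), B = c(1, 0), C = c(3, 0), D = c(0, 3),
               E = c(3, 1))
  edges <- rbind(
    data.frame(t = 1, source = "A", target = "B"),
    data.frame(t = 2, source = c("A", "A"), target = c("B", "D")),
    data.frame(t = 3, source = "B", target = "C"),
    data.frame(t = 4, source = c("B", "A"), target = c("C", "D")),
    data.frame(t = 5, source = "A", target = "D"),
    data.frame(t = 6, source = "C", target = "E"))
  edges$speed <- 1
  stn(nodes, pos, edges, observationWindow(6, 1),
      metricSpace("euclidean", 2, "m"))
}

#' Two parallel bridges with equal path betweenness, distinct efficiency
#'
#' Two disjoint three-node chains: the top chain covers 2 m hops at 1 m/s
#' (two timesteps per hop), the bottom chain covers 2 m hops at 2 m/s (one
#' timestep per hop). Each middle node carries exactly one source-target
#' pair, so their path betweenness is equal, but the bottom bridge supports
#' the faster flow and has strictly higher betweenness efficiency.
#'
#' @return A \linkS4class{SpatioTemporalNetwork}.
#' @export
equalPBDiffBEFixture <- function() {
  nodes <- c("x1", "m1", "y1", "x2", "m2", "y2")
  pos <- rbind(c(0, 10), c(2, 10), c(4, 10),
               c(0, 0), c(2, 0), c(4, 0))
  edges <- do.call(rbind, lapply(1:6, function(t) data.frame(
    t = t,
    source = c("x1", "m1", "x2", "m2"),
    target = c("m1", "y1", "m2", "y2"),
    speed = c(1, 1, 2, 2))))
  stn(nodes, pos, edges, observationWindow(6, 1),
      metricSpace("euclidean", 2, "m"))
}

#' Random geometric spatio-temporal network
#'
#' N nodes placed uniformly in a square of the given side length; every
#' ordered pair closer than \code{radius} is a candidate edge, active in
#' each snapshot independently with probability \code{p}. Each candidate
#' edge draws a log-normal propagation speed once (constant over time).
#' Fully seeded and reproducible.
#'
#' @param n number of nodes (>= 2).
#' @param nSteps number of snapshots (>= 1).
#' @param tau snapshot duration in seconds.
#' @param side square side length (metres).
#' @param radius candidate-edge distance threshold (metres).
#' @param p per-snapshot activation probability of a candidate edge.
#' @param meanlog,sdlog log-normal speed parameters (m/s); the default
#'   centres direct propagation of a radius-length edge on two timesteps.
#' @param seed integer seed.
#' @return A \linkS4class{SpatioTemporalNetwork}.
#' @export
randomGeometricSTN <- function(n, nSteps, tau = 60, side = 1000,
                               radius = 0.45 * side, p = 0.3,
                               meanlog = log(radius / (2 * tau)),
                               sdlog = 0.4, seed = 1L) {
  stopifnot(n >= 2, nSteps >= 1, p >= 0, p <= 1, radius > 0, side > 0)
  .withSeed(seed, {
    pos <- cbind(stats::runif(n, 0, side), stats::runif(n, 0, side))
    nodes <- sprintf("n%02d", seq_len(n))
    D <- as.matrix(stats::dist(pos))
    cand <- which(D > 0 & D <= radius & row(D) != col(D), arr.ind = TRUE)
    speeds <- stats::rlnorm(nrow(cand), meanlog, sdlog)
    rows <- list()
    if (nrow(cand) > 0) {
      for (i in seq_len(nSteps)) {
        on <- stats::runif(nrow(cand)) < p
        if (any(on))
          rows[[length(rows) + 1L]] <- data.frame(
            t = i, source = nodes[cand[on, 1]], target = nodes[cand[on, 2]],
            speed = speeds[on])
      }
    }
    edges <- if (length(rows)) do.call(rbind, rows) else
      data.frame(t = integer(0), source = character(0),
                 target = character(0), speed = numeric(0))
    stn(nodes, pos, edges, observationWindow(nSteps, tau),
        metricSpace("euclidean", 2, "m"))
  })
}

#' Scheduled transit-line network
#'
#' Stations arranged on lines (radial lines sharing a central hub, or a
#' single ring), with bidirectional edges between consecutive stations that
#' are active only during scheduled service steps. Per-line speeds are
#' calibrated so a hop completes in \code{hopSteps} timesteps; an optional
#' slowdown jitter and per-record service reliability make seeded ensembles
#' heterogeneous. Service gaps (e.g. night closures) are expressed through
#' \code{activeSteps}.
#'
#' @param nLines number of lines (radial geometry).
#' @param stationsPerLine stations per line including the shared hub
#'   (radial) (>= 2).
#' @param spacing distance between consecutive stations (metres).
#' @param tau snapshot duration (seconds).
#' @param nSteps number of snapshots.
#' @param hopSteps timesteps needed to traverse one hop at base speed.
#' @param geometry "radial" (lines share a hub) or "ring" (one circular
#'   line with \code{stationsPerLine} stations).
#' @param activeSteps logical vector of length \code{nSteps}; a snapshot
#'   carries service edges only where TRUE (default: always).
#' @param speedJitter in [0, 1): per-line base speed is multiplied by a
#'   uniform factor in [1 - speedJitter, 1] (slowdowns only, so the
#'   granularity bound stays respected).
#' @param reliability probability that a scheduled edge record is actually
#'   present in a snapshot.
#' @param seed integer seed (used when jitter or reliability < 1).
#' @return A \linkS4class{SpatioTemporalNetwork}.
#' @export
scheduledLinesSTN <- function(nLines = 4, stationsPerLine = 10,
                              spacing = 1000, tau = 60, nSteps = 30,
                              hopSteps = 1, geometry = c("radial", "ring"),
                              activeSteps = NULL, speedJitter = 0,
                              reliability = 1, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(stationsPerLine >= 2, nLines >= 1, nSteps >= 1,
            reliability > 0, reliability <= 1, speedJitter >= 0,
            speedJitter < 1)
  if (is.null(activeSteps)) activeSteps <- rep(TRUE, nSteps)
  stopifnot(length(activeSteps) == nSteps)
  if (!any(activeSteps)) stop("schedule has no active steps")
  .withSeed(seed, {
    if (geometry == "radial") {
      nodes <- "hub"
      pos <- matrix(c(0, 0), 1, 2)
      lineOf <- list()
      for (l in seq_len(nLines)) {
        ang <- 2 * pi * (l - 1) / nLines
        ids <- sprintf("L%d.%d", l, seq_len(stationsPerLine - 1))
        nodes <- c(nodes, ids)
        pos <- rbind(pos, cbind(cos(ang) * spacing * seq_len(stationsPerLine - 1),
                                sin(ang) * spacing * seq_len(stationsPerLine - 1)))
        lineOf[[l]] <- c("hub", ids)
      }
    } else {
      m <- stationsPerLine
      R <- spacing / (2 * sin(pi / m))
      ang <- 2 * pi * (seq_len(m) - 1) / m
      nodes <- sprintf("S%02d", seq_len(m))
      pos <- cbind(R * cos(ang), R * sin(ang))
      lineOf <- list(c(nodes, nodes[1]))
      nLines <- 1L
    }
    # ring stations sit on a circle whose chord between neighbours is
    # exactly `spacing`, so one speed calibration covers both geometries
    baseSpeed <- spacing / (tau * hopSteps)
    lineSpeed <- baseSpeed * stats::runif(nLines, 1 - speedJitter, 1)
    rows <- list()
    for (l in seq_len(nLines)) {
      seqv <- lineOf[[l]]
      src <- c(utils::head(seqv, -1), utils::tail(seqv, -1))
      dst <- c(utils::tail(seqv, -1), utils::head(seqv, -1))
      sp <- lineSpeed[l]
      for (i in which(activeSteps)) {
        keep <- if (reliability < 1)
          stats::runif(length(src)) < reliability else rep(TRUE, length(src))
        if (any(keep))
          rows[[length(rows) + 1L]] <- data.frame(
            t = i, source = src[keep], target = dst[keep], speed = sp)
      }
    }
    edges <- unique(do.call(rbind, rows))
    stn(nodes, pos, edges, observationWindow(nSteps, tau),
        metricSpace("euclidean", 2, "m"))
  })
}

#' Connectome-like static-topology network
#'
#' A spatially embedded directed network with identical snapshots (static
#' topology, temporal correlation 1). Edges are labelled by connection type
#' (chemical, electrical or both) and carry speeds calibrated so that the
#' direct propagation delay D/S of every edge falls inside
#' \code{delayRange}: electrical connections draw from the faster half of
#' the range, chemical from the slower half, mixed from the whole range.
#'
#' @param n number of nodes.
#' @param meanDegree expected out-degree of the random static topology.
#' @param delayRange length-2 numeric, direct-propagation delay bounds in
#'   seconds (default 10-30 ms).
#' @param tau snapshot duration in seconds (default 10 ms).
#' @param nSteps number of snapshots.
#' @param extent side of the square embedding (metres; default 1 mm).
#' @param seed integer seed.
#' @return A \linkS4class{SpatioTemporalNetwork} whose edge delays all lie
#'   within \code{delayRange}.
#' @export
connectomeSTN <- function(n = 50, meanDegree = 4,
                          delayRange = c(0.010, 0.030), tau = 0.010,
                          nSteps = 20, extent = 1e-3, seed = 1L) {
  stopifnot(n >= 2, delayRange[1] > 0, delayRange[2] > delayRange[1])
  .withSeed(seed, {
    nodes <- sprintf("neu%03d", seq_len(n))
    pos <- cbind(stats::runif(n, 0, extent), stats::runif(n, 0, extent))
    pEdge <- min(1, meanDegree / (n - 1))
    A <- matrix(stats::runif(n * n) < pEdge, n, n)
    diag(A) <- FALSE
    idx <- which(A, arr.ind = TRUE)
    type <- sample(c("chemical", "electrical", "both"), nrow(idx),
                   replace = TRUE, prob = c(0.5, 0.3, 0.2))
    mid <- mean(delayRange)
    delay <- ifelse(type == "electrical",
                    stats::runif(nrow(idx), delayRange[1], mid),
                    ifelse(type == "chemical",
                           stats::runif(nrow(idx), mid, delayRange[2]),
                           stats::runif(nrow(idx), delayRange[1],
                                        delayRange[2])))
    D <- as.matrix(stats::dist(pos))
    sp <- D[idx] / delay
    edges <- do.call(rbind, lapply(seq_len(nSteps), function(i)
      data.frame(t = i, source = nodes[idx[, 1]], target = nodes[idx[, 2]],
                 speed = sp)))
    net <- stn(nodes, pos, edges, observationWindow(nSteps, tau),
               metricSpace("euclidean", 2, "m"))
    net@cache$edgeType <- type
    net
  })
}

#' Intermittent contact network with instantaneous links
#'
#' Emulates proximity/communication logs: every unordered node pair is
#' independently in contact in each snapshot with probability \code{p};
#' contacts are bidirectional edges with infinite propagation speed (a hop
#' still takes one timestep to be forwarded). Optionally nodes perform a
#' Gaussian random walk between snapshots.
#'
#' @param n number of nodes.
#' @param nSteps number of snapshots.
#' @param tau snapshot duration (seconds).
#' @param p per-snapshot contact probability per pair.
#' @param side square side (metres).
#' @param mobility standard deviation of per-step random-walk displacement
#'   (metres); 0 keeps positions static.
#' @param seed integer seed.
#' @return A \linkS4class{SpatioTemporalNetwork}.
#' @export
contactSTN <- function(n = 20, nSteps = 30, tau = 60, p = 0.05,
                       side = 5000, mobility = 0, seed = 1L) {
  stopifnot(n >= 2, nSteps >= 1, p >= 0, p <= 1)
  .withSeed(seed, {
    nodes <- sprintf("p%02d", seq_len(n))
    base <- cbind(stats::runif(n, 0, side), stats::runif(n, 0, side))
    if (mobility > 0) {
      pos <- array(0, dim = c(n, 2, nSteps))
      pos[, , 1] <- base
      for (i in seq_len(nSteps)[-1])
        pos[, , i] <- pos[, , i - 1] +
          matrix(stats::rnorm(2 * n, 0, mobility), n, 2)
    } else pos <- base
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    rows <- list()
    for (i in seq_len(nSteps)) {
      on <- stats::runif(nrow(pairs)) < p
      if (any(on)) {
        a <- nodes[pairs[on, 1]]; b <- nodes[pairs[on, 2]]
        rows[[length(rows) + 1L]] <- data.frame(
          t = i, source = c(a, b), target = c(b, a), speed = Inf)
      }
    }
    edges <- if (length(rows)) do.call(rbind, rows) else
      data.frame(t = integer(0), source = character(0),
                 target = character(0), speed = numeric(0))
    stn(nodes, pos, edges, observationWindow(nSteps, tau),
        metricSpace("euclidean", 2, "m"))
  })
}
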