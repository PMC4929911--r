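#' Deactivate a set of nodes
#'
#' Complete node failure: every edge to or from a deactivated node is
#' removed from every snapshot. The node set (and N) is unchanged;
#' positions are retained.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param nodes character vector of node ids to deactivate (may be empty).
#' @return A \linkS4class{SpatioTemporalNetwork} with the edges removed.
#' @export
deactivate <- function(net, nodes) {
  idx <- match(nodes, net@nodes)
  if (anyNA(idx)) stop("unknown node id(s): ",
                       paste(nodes[is.na(idx)], collapse = ", "))
  if (length(idx) == 0) return(net)
  snaps <- lapply(net@snapshots, function(S) {
    S[idx, ] <- 0
    S[, idx] <- 0
    methods::as(Matrix::drop0(S), "CsparseMatrix")
  })
  methods::initialize(net, snapshots = snaps)
}

.asAllPairs <- function(x, window = NULL) {
  if (is.list(x) && !is.null(x$latSteps)) return(x)
  allPairs(x, window)
}

#' Strong components of the spatio-temporal reachability relation
#'
#' A strong component is a node set in which a spatio-temporal path exists
#' between every ordered pair. Because temporal reachability is
#' non-transitive, this is computed with the affine-graph method: build the
#' undirected affine graph with an edge between v and w iff each reaches
#' the other within the window, and take its maximal cliques as the strong
#' components. The giant strong size S is the largest clique as a fraction
#' of all nodes. The weak counterpart links v and w when at least one
#' direction is reachable.
#'
#' @param x a \linkS4class{SpatioTemporalNetwork} or a precomputed
#'   \code{\link{allPairs}} result.
#' @param window snapshot window (ignored when \code{x} is an allPairs
#'   result).
#' @return list with \code{S} (giant strong fraction), \code{Sweak},
#'   \code{giant} (node indices of one largest strong component) and
#'   \code{mutual} (the affine graph's adjacency matrix).
#' @export
strongComponents <- function(x, window = NULL) {
  ap <- .asAllPairs(x, window)
  reach <- ap$reach
  diag(reach) <- FALSE
  n <- nrow(reach)
  mutual <- reach & t(reach)
  either <- reach | t(reach)
  gm <- igraph::graph_from_adjacency_matrix(mutual * 1, mode = "undirected")
  giant <- igraph::largest_cliques(gm)[[1]]
  gw <- igraph::graph_from_adjacency_matrix(either * 1, mode = "undirected")
  Sweak <- igraph::clique_num(gw) / n
  list(S = length(giant) / n, Sweak = Sweak,
       giant = sort(as.integer(giant)), mutual = mutual)
}

#' Temporal or spatial efficiency
#'
#' Temporal efficiency is the mean reciprocal temporal distance over all
#' ordered node pairs, with distances in timestep units, so it lies in
#' [0, 1]: it is 1 iff every ordered pair completes direct propagation in a
#' single timestep and 0 if no propagation succeeds. Spatial efficiency is
#' the mean reciprocal spatial distance (units: reciprocal length).
#' Unreachable pairs contribute 0.
#'
#' @inheritParams strongComponents
#' @param kind "temporal" or "spatial".
#' @return A single number.
#' @export
efficiency <- function(x, window = NULL, kind = c("temporal", "spatial")) {
  kind <- match.arg(kind)
  ap <- .asAllPairs(x, window)
  M <- if (kind == "temporal") ap$latSteps else ap$sdist
  n <- nrow(M)
  if (n < 2) stop("efficiency requires at least two nodes")
  off <- M[row(M) != col(M)]
  inv <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  sum(inv) / (n * (n - 1))
}

# giant strong fraction only (cheaper than strongComponents: no weak
# counterpart, no membership extraction) -- the robustness sweeps call this
# once per realization/removal
.giantStrongSize <- function(ap) {
  reach <- ap$reach
  diag(reach) <- FALSE
  mutual <- reach & t(reach)
  gm <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected")
  igraph::clique_num(gm) / nrow(reach)
}

.curveMeasures <- function(net, window, baseline) {
  ap <- allPairs(net, window)
  c(S = .giantStrongSize(ap),
    Rlambda = if (baseline["Elambda"] > 0)
      efficiency(ap, kind = "temporal") / baseline["Elambda"] else 0,
    Rsigma = if (baseline["Esigma"] > 0)
      efficiency(ap, kind = "spatial") / baseline["Esigma"] else 0,
    use.names = FALSE)
}

.baselineOf <- function(net, window) {
  ap <- allPairs(net, window)
  c(Elambda = efficiency(ap, kind = "temporal"),
    Esigma = efficiency(ap, kind = "spatial"),
    S = .giantStrongSize(ap))
}

# All-pairs distances recomputed from prebuilt dense engine inputs with a
# node subset removed; avoids rebuilding sparse snapshots per realization.
.apWithRemoved <- function(inp, n, removedIdx) {
  speeds <- inp$speeds
  if (length(removedIdx))
    speeds <- lapply(speeds, function(m) {
      m[removedIdx, ] <- 0
      m[, removedIdx] <- 0
      m
    })
  latSteps <- matrix(Inf, n, n)
  sdist <- matrix(Inf, n, n)
  for (v in setdiff(seq_len(n), removedIdx)) {
    res <- cpp_propagate(speeds, inp$dists, inp$tau, v - 1L, TRUE, FALSE,
                         FALSE)
    latSteps[v, ] <- ifelse(is.na(res$arrival), Inf, res$arrival)
    sdist[v, ] <- res$sdist
  }
  diag(latSteps) <- 0
  diag(sdist) <- 0
  list(latSteps = latSteps, sdist = sdist, reach = is.finite(latSteps),
       tau = inp$tau)
}

.measuresWithRemoved <- function(inp, n, removedIdx, baseline) {
  ap <- .apWithRemoved(inp, n, removedIdx)
  c(S = .giantStrongSize(ap),
    Rlambda = if (baseline["Elambda"] > 0)
      efficiency(ap, kind = "temporal") / baseline["Elambda"] else 0,
    Rsigma = if (baseline["Esigma"] > 0)
      efficiency(ap, kind = "spatial") / baseline["Esigma"] else 0,
    use.names = FALSE)
}

#' Robustness under uniform random node failure
#'
#' For each failure probability f, draws independent realizations in which
#' each node fails independently with probability f (expected f * N
#' failures; \code{exactCount = TRUE} instead removes exactly
#' \code{ceiling(f * N)} uniformly chosen nodes), recomputes the giant
#' strong component size S and the relative efficiencies R^lambda and
#' R^sigma, and reports their mean, standard deviation and standard error.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param window snapshot window (default full).
#' @param fractions numeric failure probabilities in [0, 1].
#' @param realizations number of random realizations per fraction.
#' @param seed integer seed; the curve is fully reproducible.
#' @param exactCount use fixed-size instead of Bernoulli deactivation sets.
#' @return A \linkS4class{RobustnessCurve} (strategy "ERR").
#' @export
randomErrorCurve <- function(net, window = NULL, fractions = seq(0, 1, 0.1),
                             realizations = 100, seed = 1L,
                             exactCount = FALSE) {
  window <- .checkWindow(net, window)
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  stopifnot(realizations >= 1)
  baseline <- .baselineOf(net, window)
  n <- nNodes(net)
  inp <- .engineInputs(net, window)
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  means <- sds <- ses <- matrix(0, length(fractions), 3,
                                dimnames = list(NULL, c("S", "Rlambda",
                                                        "Rsigma")))
  for (k in seq_along(fractions)) {
    f <- fractions[k]
    deterministic <- !exactCount && (f == 0 || f == 1)
    reps <- if (deterministic) 1L else realizations
    vals <- matrix(0, reps, 3)
    for (r in seq_len(reps)) {
      fail <- if (exactCount) {
        nf <- ceiling(f * n)
        if (nf > 0) sample.int(n, nf) else integer(0)
      } else if (f == 0) integer(0)
      else if (f == 1) seq_len(n)
      else which(stats::runif(n) < f)
      vals[r, ] <- .measuresWithRemoved(inp, n, fail, baseline)
    }
    if (deterministic) vals <- vals[rep(1L, realizations), , drop = FALSE]
    means[k, ] <- colMeans(vals)
    sds[k, ] <- apply(vals, 2, stats::sd)
    ses[k, ] <- sds[k, ] / sqrt(realizations)
  }
  new("RobustnessCurve", strategy = "ERR", window = window,
      fractions = fractions, S = means[, "S"], Rlambda = means[, "Rlambda"],
      Rsigma = means[, "Rsigma"], sd = sds, se = ses,
      realizations = as.integer(realizations), baseline = baseline,
      removalOrder = character(0))
}

.intactRanking <- function(net, window, strategy) {
  scores <- switch(strategy,
                   TC = temporalInCloseness(net, window)@scores,
                   ID = degreeScores(net, "in")@scores,
                   OD = degreeScores(net, "out")@scores,
                   PTPB = pureTemporalPathBetweenness(net, window)@scores)
  net@nodes[order(-scores, net@nodes)]
}

#' Robustness under systematic attack
#'
#' Deactivates nodes one at a time according to a centrality-based strategy
#' and records S, R^lambda and R^sigma after each failure (at fractions
#' k / N, k = 0..N). TC, ID, OD and PTPB rank nodes once on the intact
#' network; the betweenness attacks PB and BE recompute their ranking on
#' the damaged network after every failure. Ties are broken by node
#' identifier, so curves are deterministic.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @param window snapshot window (default full).
#' @param strategy one of "TC", "PB", "BE", "ID", "OD", "PTPB".
#' @return A \linkS4class{RobustnessCurve}.
#' @export
attackCurve <- function(net, window = NULL,
                        strategy = c("TC", "PB", "BE", "ID", "OD", "PTPB")) {
  strategy <- match.arg(strategy)
  window <- .checkWindow(net, window)
  n <- nNodes(net)
  baseline <- .baselineOf(net, window)
  greedy <- strategy %in% c("PB", "BE")
  fixedOrder <- if (!greedy) .intactRanking(net, window, strategy)
  fractions <- (0:n) / n
  S <- Rl <- Rs <- numeric(n + 1)
  S[1] <- baseline["S"]; Rl[1] <- 1; Rs[1] <- 1
  removed <- character(0)
  current <- net
  for (k in seq_len(n)) {
    target <- if (greedy) {
      ap <- allPairs(current, window, centrality = TRUE)
      sc <- if (strategy == "PB") ap$pb else ap$be
      remaining <- setdiff(net@nodes, removed)
      remaining[order(-sc[remaining], remaining)][1]
    } else fixedOrder[k]
    removed <- c(removed, target)
    current <- deactivate(current, target)
    m <- .curveMeasures(current, window, baseline)
    S[k + 1] <- m[1]; Rl[k + 1] <- m[2]; Rs[k + 1] <- m[3]
  }
  new("RobustnessCurve", strategy = strategy, window = window,
      fractions = fractions, S = S, Rlambda = Rl, Rsigma = Rs,
      sd = matrix(0, n + 1, 3), se = matrix(0, n + 1, 3),
      realizations = 1L, baseline = baseline, removalOrder = removed)
}

#' Area under a robustness curve
#'
#' Trapezoidal area of the chosen measure over f in [0, 1]. Fractions
#' outside the computed grid are extended by the nearest computed value
#' (constant extrapolation to f = 0 and f = 1); this integration convention
#' is recorded in the result's attributes. Lower areas indicate more
#' aggressive attacks.
#'
#' @param curve a \linkS4class{RobustnessCurve} (at least 2 grid points).
#' @param measure "S", "Rlambda" or "Rsigma".
#' @return Numeric area, with attribute \code{convention}.
#' @export
curveAUC <- function(curve, measure = c("S", "Rlambda", "Rsigma")) {
  measure <- match.arg(measure)
  f <- curve@fractions
  y <- slot(curve, measure)
  if (length(f) < 2) stop("curve needs at least 2 grid points")
  o <- order(f)
  f <- f[o]; y <- y[o]
  if (f[1] > 0) { f <- c(0, f); y <- c(y[1], y) }
  if (f[length(f)] < 1) { f <- c(f, 1); y <- c(y, y[length(y)]) }
  auc <- sum(diff(f) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  attr(auc, "convention") <- "trapezoid; constant extrapolation to f=0 and f=1"
  auc
}
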