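#' Topological temporal correlation between consecutive snapshots
#'
#' Per-node topological overlap between snapshots i and i+1 on the
#' unweighted adjacency,
#' \code{C_v(i) = sum_w a_vw[i] a_vw[i+1] / sqrt(sum_w a_vw[i] *
#' sum_w a_vw[i+1])}, averaged over the nodes for which it is defined
#' (0/0 terms are skipped) and then over i = 1..T-1. A network whose
#' snapshots all share one edge set has correlation exactly 1.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork} with \code{T >= 2}.
#' @return Numeric in [0, 1] (NaN if no term is defined).
#' @export
temporalCorrelation <- function(net) {
  Tn <- nSnapshots(net)
  if (Tn < 2) stop("temporal correlation requires T >= 2")
  adj <- lapply(net@snapshots, function(S) (S != 0) * 1)
  perStep <- vapply(seq_len(Tn - 1), function(i) {
    A <- adj[[i]]; B <- adj[[i + 1]]
    num <- Matrix::rowSums(A * B)
    den <- sqrt(Matrix::rowSums(A) * Matrix::rowSums(B))
    ok <- den > 0
    if (!any(ok)) return(NaN)
    mean(num[ok] / den[ok])
  }, numeric(1))
  mean(perStep[!is.nan(perStep)])
}

#' Topological and weight reciprocity
#'
#' Per snapshot with at least one edge: topological reciprocity r is the
#' fraction of directed edges whose reverse also exists in that snapshot;
#' weight reciprocity rho is sum(min(S_vw, S_wv)) / sum(max(S_vw, S_wv))
#' over dyads with at least one edge. Both are averaged over non-empty
#' snapshots. For the weight ratio, infinite speeds are capped at twice the
#' largest finite speed in the network (1 when none), so fully
#' instantaneous dyads count as reciprocated.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @return list with elements \code{r} and \code{rho} (each in [0, 1];
#'   NaN when no snapshot has edges).
#' @export
reciprocity <- function(net) {
  finiteMax <- 0
  for (S in net@snapshots) {
    fx <- S@x[is.finite(S@x)]
    if (length(fx)) finiteMax <- max(finiteMax, fx)
  }
  cap <- if (finiteMax > 0) 2 * finiteMax else 1
  rs <- rhos <- numeric(0)
  for (S in net@snapshots) {
    if (length(S@x) == 0) next
    A <- (S != 0) * 1
    nEdges <- sum(A)
    recip <- sum(A * Matrix::t(A))
    rs <- c(rs, recip / nEdges)
    W <- as.matrix(S)
    W[is.infinite(W)] <- cap
    Wt <- t(W)
    up <- upper.tri(W)
    any1 <- (W[up] > 0) | (Wt[up] > 0)
    mn <- pmin(W[up], Wt[up])[any1]
    mx <- pmax(W[up], Wt[up])[any1]
    rhos <- c(rhos, sum(mn) / sum(mx))
  }
  if (length(rs) == 0) return(list(r = NaN, rho = NaN))
  list(r = mean(rs), rho = mean(rhos))
}

#' Radius of gyration of node trajectories
#'
#' Per node, the root-mean-square metric distance of its per-snapshot
#' positions from their centroid. For the geodesic metric the computation
#' is carried out in a local equirectangular projection around the
#' trajectory's mean latitude. Static nodes have radius exactly 0.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @return list with per-node vector \code{perNode} and scalar \code{mean},
#'   in the metric's length units.
#' @export
radiusOfGyration <- function(net) {
  n <- nNodes(net)
  Tn <- nSnapshots(net)
  out <- numeric(n)
  if (!net@staticPositions) {
    for (v in seq_len(n)) {
      traj <- t(net@positions[v, , , drop = TRUE])
      if (is.null(dim(traj))) traj <- matrix(traj, ncol = 1)
      if (net@metric@kind == "geodesic") {
        # local projection: metres east/north about the mean latitude
        R <- 6371008.8
        latRad <- traj[, 1] * pi / 180
        lonRad <- traj[, 2] * pi / 180
        traj <- cbind(R * lonRad * cos(mean(latRad)), R * latRad)
        if (net@metric@units == "km") traj <- traj / 1000
      }
      ctr <- colMeans(traj)
      out[v] <- sqrt(mean(rowSums(sweep(traj, 2, ctr)^2)))
    }
  }
  names(out) <- net@nodes
  list(perNode = out, mean = mean(out))
}

#' Median propagation speed
#'
#' Median over all finite edge-speed records across all snapshots, in
#' length units per second. When every edge is instantaneous the result is
#' \code{Inf} (printed as "inst."); for mixed networks the attribute
#' \code{infiniteFraction} reports the share of infinite-speed records.
#'
#' @param net a \linkS4class{SpatioTemporalNetwork} with at least one edge.
#' @return Numeric (possibly Inf) with attribute \code{infiniteFraction}.
#' @export
medianSpeed <- function(net) {
  sp <- unlist(lapply(net@snapshots, function(S) S@x), use.names = FALSE)
  if (length(sp) == 0) stop("network has no edges")
  fin <- sp[is.finite(sp)]
  out <- if (length(fin) == 0) Inf else stats::median(fin)
  attr(out, "infiniteFraction") <- mean(is.infinite(sp))
  out
}

#' Descriptive summary of a spatio-temporal network
#'
#' @param net a \linkS4class{SpatioTemporalNetwork}.
#' @return A \linkS4class{NetworkSummary} collecting N, aggregate edge
#'   count and density, tau, T, duration, temporal correlation, topological
#'   and weight reciprocity, mean radius of gyration and median speed.
#' @export
networkSummary <- function(net) {
  g <- aggregateGraph(net)
  rec <- reciprocity(net)
  gyr <- radiusOfGyration(net)
  med <- tryCatch(medianSpeed(net), error = function(e) NaN)
  new("NetworkSummary", values = list(
    N = nNodes(net),
    nEdgesAggregate = igraph::graph_attr(g, "nEdges"),
    density = igraph::graph_attr(g, "density"),
    tau = net@window@tau,
    nSteps = nSnapshots(net),
    duration = nSnapshots(net) * net@window@tau,
    temporalCorrelation = if (nSnapshots(net) >= 2) temporalCorrelation(net)
                          else NA_real_,
    topologicalReciprocity = rec$r,
    weightReciprocity = rec$rho,
    radiusOfGyration = gyr$mean,
    medianSpeed = as.numeric(med),
    infiniteSpeedFraction = attr(med, "infiniteFraction")))
}

setMethod("show", "NetworkSummary", function(object) {
  v <- object@values
  cat("NetworkSummary\n")
  cat(sprintf("  N = %d, |E*| = %d (density %.4f)\n", v$N,
              v$nEdgesAggregate, v$density))
  cat(sprintf("  tau = %g s, T = %d, duration = %g s\n", v$tau, v$nSteps,
              v$duration))
  cat(sprintf("  temporal correlation C = %.3f\n", v$temporalCorrelation))
  cat(sprintf("  reciprocity r = %.3f, rho = %.3f\n",
              v$topologicalReciprocity, v$weightReciprocity))
  cat(sprintf("  mean radius of gyration = %g\n", v$radiusOfGyration))
  ms <- if (is.infinite(v$medianSpeed)) "inst." else
    sprintf("%g %s/s", v$medianSpeed, "unit")
  cat(sprintf("  median speed = %s\n", ms))
})
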