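#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib stnet, .registration = TRUE
NULL

#' Observation window of a spatio-temporal network
#'
#' Describes the discrete time axis over which a network is observed: a start
#' time \code{t1} (seconds; any epoch convention), a number of snapshots
#' \code{nSteps}, and the temporal granularity \code{tau} (seconds), i.e. the
#' fixed duration of each snapshot. Snapshot \code{i} (1-based) covers the
#' half-open real interval \code{[t1 + (i-1)*tau, t1 + i*tau)}.
#'
#' @slot t1 numeric start time in seconds.
#' @slot nSteps integer number of snapshots (\code{T >= 1}).
#' @slot tau numeric snapshot duration in seconds (\code{> 0}).
#' @export
setClass("ObservationWindow",
         representation(t1 = "numeric", nSteps = "integer", tau = "numeric"),
         validity = function(object) {
           if (length(object@tau) != 1 || !is.finite(object@tau) || object@tau <= 0)
             return("tau must be a single positive number (seconds)")
           if (length(object@nSteps) != 1 || is.na(object@nSteps) || object@nSteps < 1L)
             return("nSteps must be a positive integer")
           if (length(object@t1) != 1 || !is.finite(object@t1))
             return("t1 must be a single finite number")
           TRUE
         })

#' Metric space in which network nodes are embedded
#'
#' Either a k-dimensional Euclidean space or the WGS-84 ellipsoid (geodesic
#' distances; coordinates are latitude/longitude in decimal degrees). The
#' distance function is non-negative, symmetric and zero only for identical
#' coordinates.
#'
#' @slot kind "euclidean" or "geodesic".
#' @slot dimension integer coordinate dimension (2 for geodesic).
#' @slot units length unit label ("m" or "km") in which distances are
#'   expressed; speeds are in units per second.
#' @export
setClass("MetricSpace",
         representation(kind = "character", dimension = "integer",
                        units = "character"),
         validity = function(object) {
           if (!object@kind %in% c("euclidean", "geodesic"))
             return("kind must be 'euclidean' or 'geodesic'")
           if (object@kind == "geodesic" && object@dimension != 2L)
             return("geodesic metric requires dimension 2 (lat, lon)")
           if (object@dimension < 1L) return("dimension must be >= 1")
           if (!object@units %in% c("m", "km"))
             return("units must be 'm' or 'km'")
           TRUE
         })

#' Time-varying spatially embedded network
#'
#' The central container: a fixed node set observed over \code{T} equal-width
#' snapshots. Each snapshot holds a directed graph whose edges carry a
#' propagation speed (length units per second, possibly \code{Inf} for
#' instantaneous interaction); an absent edge is encoded as speed 0. Nodes
#' occupy positions in a metric space, either static or per-snapshot
#' trajectories; no two nodes may share a position within a snapshot.
#'
#' @slot nodes character vector of node identifiers (defines node order).
#' @slot positions numeric array \code{N x k x T} of coordinates.
#' @slot staticPositions logical; TRUE when positions do not vary over time
#'   (enables distance-matrix caching).
#' @slot metric a \linkS4class{MetricSpace}.
#' @slot snapshots list of \code{T} sparse \code{dgCMatrix} speed matrices.
#' @slot window an \linkS4class{ObservationWindow}.
#' @slot cache environment used internally for distance-matrix memoisation.
#' @export
setClass("SpatioTemporalNetwork",
         representation(nodes = "character", positions = "array",
                        staticPositions = "logical", metric = "MetricSpace",
                        snapshots = "list", window = "ObservationWindow",
                        cache = "environment"),
         validity = function(object) {
           n <- length(object@nodes)
           if (n < 1L) return("at least one node required")
           if (anyDuplicated(object@nodes)) return("duplicate node identifiers")
           dp <- dim(object@positions)
           if (length(dp) != 3L || dp[1] != n)
             return("positions must be an N x k x T array")
           if (dp[2] != object@metric@dimension)
             return("position dimension does not match metric space")
           Tn <- object@window@nSteps
           if (dp[3] != Tn) return("positions third dimension must equal nSteps")
           if (length(object@snapshots) != Tn)
             return("snapshots list length must equal nSteps")
           for (i in seq_len(Tn)) {
             S <- object@snapshots[[i]]
             if (!methods::is(S, "sparseMatrix") || nrow(S) != n || ncol(S) != n)
               return(sprintf("snapshot %d is not an N x N sparse matrix", i))
             if (any(Matrix::diag(S) != 0))
               return(sprintf("snapshot %d contains self-edges", i))
             sx <- S@x
             if (length(sx) && any(sx < 0))
               return(sprintf("snapshot %d contains negative speeds", i))
           }
           TRUE
         })

#' Outcome of structural validation of a network
#'
#' Collects findings at "error" or "warning" severity; the report fails iff
#' at least one error-severity finding is present.
#'
#' @slot findings data.frame with columns severity, code, message.
#' @slot pass logical.
#' @export
setClass("ValidationReport",
         representation(findings = "data.frame", pass = "logical"))

#' State of the constrained-propagation process from one origin
#'
#' Tracks, for a single origin and observation window, the reachability set
#' (as per-node arrival snapshot indices) and the progress matrix P whose
#' entry (v, w) is the distance accumulated by direct propagation from v to w.
#'
#' @slot origin character origin node id.
#' @slot nodes character node ids (network order).
#' @slot windowStart integer snapshot index at which propagation started.
#' @slot step integer snapshot index of the state (the last step applied).
#' @slot arrival integer vector: snapshot index at which each node joined the
#'   reachability set, NA if not (yet) reached.
#' @slot P numeric N x N progress matrix (length units).
#' @slot preds list per node: data.frame(pred, step, hop) of predecessor
#'   triples recorded at the node's arrival step.
#' @export
setClass("PropagationState",
         representation(origin = "character", nodes = "character",
                        windowStart = "integer", step = "integer",
                        arrival = "integer", P = "matrix", preds = "list"))

#' Per-origin spatio-temporal shortest-path summary
#'
#' For a fixed origin and window: per destination, the temporal distance
#' (latency of the spatio-temporally shortest path, seconds; Inf when
#' unreachable), the spatial distance (its spatial length, length units), the
#' number of spatio-temporally shortest paths, and the predecessor DAG
#' restricted to those paths.
#'
#' @slot origin character origin id.
#' @slot nodes character node ids.
#' @slot window integer length-2 (start, end) snapshot indices.
#' @slot arrival integer arrival snapshot index per node (NA unreachable).
#' @slot latency numeric seconds from window start (0 at origin, Inf
#'   unreachable).
#' @slot sdist numeric spatial length (0 at origin, Inf unreachable).
#' @slot sigma numeric count of spatio-temporally shortest paths (1 at
#'   origin, 0 unreachable).
#' @slot dag list per node of integer predecessor indices on shortest paths.
#' @slot hops list per node of hop distances aligned with \code{dag}.
#' @export
setClass("ShortestPathSummary",
         representation(origin = "character", nodes = "character",
                        window = "integer", arrival = "integer",
                        latency = "numeric", sdist = "numeric",
                        sigma = "numeric", dag = "list", hops = "list"))

#' Node centrality scores
#'
#' @slot measure one of "TC", "PB", "BE", "PTPB", "ID", "OD".
#' @slot window integer length-2 snapshot window the scores refer to.
#' @slot scores named numeric vector, one score per node.
#' @export
setClass("CentralityScores",
         representation(measure = "character", window = "integer",
                        scores = "numeric"))

#' Robustness curve under node deactivation
#'
#' Giant strong component size S, temporal robustness R^lambda and spatial
#' robustness R^sigma as functions of the deactivated fraction f, for a
#' deterministic attack strategy or random error (with realization
#' statistics).
#'
#' @slot strategy one of "ERR", "TC", "PB", "BE", "ID", "OD", "PTPB".
#' @slot window integer length-2 snapshot window.
#' @slot fractions numeric grid of deactivation fractions.
#' @slot S numeric giant strong component size at each fraction.
#' @slot Rlambda numeric relative temporal efficiency at each fraction.
#' @slot Rsigma numeric relative spatial efficiency at each fraction.
#' @slot sd numeric matrix (3 columns S, Rlambda, Rsigma) of realization
#'   standard deviations; zero rows for deterministic strategies.
#' @slot se numeric matrix of standard errors (same layout).
#' @slot realizations integer realization count (1 for deterministic).
#' @slot baseline named numeric: intact-network Elambda, Esigma, S.
#' @slot removalOrder character deactivation order (deterministic
#'   strategies; empty for ERR).
#' @export
setClass("RobustnessCurve",
         representation(strategy = "character", window = "integer",
                        fractions = "numeric", S = "numeric",
                        Rlambda = "numeric", Rsigma = "numeric",
                        sd = "matrix", se = "matrix",
                        realizations = "integer", baseline = "numeric",
                        removalOrder = "character"))

#' Descriptive summary of a spatio-temporal network
#'
#' Mirrors a per-network descriptive record: size, aggregate edge count and
#' density, window metadata, topological temporal correlation between
#' consecutive snapshots, topological and weight reciprocity, mean radius of
#' gyration of node trajectories, and the median finite propagation speed
#' (Inf when all speeds are instantaneous).
#'
#' @slot values named list of the summary fields.
#' @export
setClass("NetworkSummary", representation(values = "list"))
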