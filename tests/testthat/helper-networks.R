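# Small network builders used across tests.

# Build a network from an edge data.frame with default unit geometry:
# nodes on a line, 1 unit apart, unless positions are given.
mkNet <- function(nodes, edges, nSteps, tau = 1, positions = NULL,
                  units = "m") {
  if (is.null(positions))
    positions <- cbind(seq_along(nodes) - 1, 0)
  stn(nodes, positions, edges, observationWindow(nSteps, tau),
      metricSpace("euclidean", 2, units))
}

# Directed chain A -> B -> C ... with persistent edges; speeds chosen so a
# hop completes in exactly `hopSteps` timesteps.
chainNet <- function(k = 3, nSteps = 6, tau = 1, hopSteps = 1) {
  nodes <- LETTERS[seq_len(k)]
  edges <- do.call(rbind, lapply(seq_len(nSteps), function(t) data.frame(
    t = t, source = nodes[-k], target = nodes[-1],
    speed = 1 / (tau * hopSteps))))
  mkNet(nodes, edges, nSteps, tau)
}

# Complete one-step network: every ordered pair has a persistent edge fast
# enough to complete direct propagation in a single timestep.
completeOneStepNet <- function(k = 4, nSteps = 3, tau = 1) {
  nodes <- LETTERS[seq_len(k)]
  pos <- cbind(seq_len(k) - 1, 0)
  prs <- expand.grid(s = seq_len(k), d = seq_len(k))
  prs <- prs[prs$s != prs$d, ]
  maxD <- k - 1
  edges <- do.call(rbind, lapply(seq_len(nSteps), function(t) data.frame(
    t = t, source = nodes[prs$s], target = nodes[prs$d],
    speed = maxD / tau)))
  mkNet(nodes, edges, nSteps, tau, positions = pos)
}

# Random instance used by oracle-equivalence properties: small N and T,
# moderate density, log-normal speeds.
smallRandomNet <- function(seed, nMax = 7, tMax = 10) {
  set.seed(seed)
  n <- sample(4:nMax, 1)
  nSteps <- sample(5:tMax, 1)
  randomGeometricSTN(n, nSteps, tau = 60, side = 1000, radius = 600,
                     p = 0.35, seed = seed + 10000L)
}
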