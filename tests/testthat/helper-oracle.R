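# Exhaustive spatio-temporal path oracle.
#
# Enumerates every distinct-node sequence from an origin, simulating each
# hop's progress accumulation directly from the update rules (increment
# min(tau*S, remaining distance) while the edge is present, reset to zero
# when absent, arrival when accumulated progress meets the pair distance).
# A sequence is a valid trace of the propagation process only if every
# prefix reaches its endpoint at that node's earliest arrival over all
# sequences; earliest arrivals are computed from the enumeration itself,
# independently of the engine.

oracleHop <- function(speeds, D, tau, v, w, startOff, steps) {
  P <- 0
  if (startOff + 1 > steps - 1) return(NULL)
  for (s in (startOff + 1):(steps - 1)) {
    sp <- speeds[[s + 1]][v, w]
    d <- D[v, w]
    if (sp > 0) {
      q <- max(0, d - P)
      P <- P + min(tau * sp, q)
      if (P >= d - 1e-9 * max(1, d)) return(list(arr = s, hopd = P))
    } else {
      P <- 0
    }
  }
  NULL
}

# All feasible sequences from origin v0 (window offsets 0..steps-1).
oracleSequences <- function(speeds, D, tau, v0) {
  steps <- length(speeds)
  n <- nrow(D)
  seqs <- list()
  rec <- function(nodesSeq, arrSeq, hopSeq) {
    last <- nodesSeq[length(nodesSeq)]
    for (w in setdiff(seq_len(n), nodesSeq)) {
      h <- oracleHop(speeds, D, tau, last, w, arrSeq[length(arrSeq)], steps)
      if (!is.null(h)) {
        ns <- c(nodesSeq, w)
        as2 <- c(arrSeq, h$arr)
        hs <- c(hopSeq, h$hopd)
        seqs[[length(seqs) + 1L]] <<- list(nodes = ns, arr = as2, hop = hs)
        rec(ns, as2, hs)
      }
    }
  }
  rec(v0, 0L, numeric(0))
  seqs
}

# Per-origin oracle summary: earliest arrivals (timestep offsets), minimal
# spatial lengths, shortest-path counts and interior-node sets of the
# spatio-temporally shortest paths.
oracleOrigin <- function(net, v0, window = NULL, spatialTiebreak = TRUE) {
  if (is.null(window)) window <- c(1L, nSnapshots(net))
  n <- nNodes(net)
  tau <- obsWindow(net)@tau
  speeds <- lapply(window[1]:window[2],
                   function(i) as.matrix(snapshotSpeeds(net, i)))
  D <- distanceMatrix(net, 1L)
  seqs <- oracleSequences(speeds, D, tau, v0)
  earliest <- rep(Inf, n)
  earliest[v0] <- 0
  for (sq in seqs) {
    u <- sq$nodes[length(sq$nodes)]
    earliest[u] <- min(earliest[u], sq$arr[length(sq$arr)])
  }
  valid <- Filter(function(sq) all(sq$arr[-1] == earliest[sq$nodes[-1]]),
                  seqs)
  sdist <- rep(Inf, n)
  sdist[v0] <- 0
  sigma <- rep(0, n)
  sigma[v0] <- 1
  interior <- vector("list", n)
  for (u in seq_len(n)) {
    vu <- Filter(function(sq) sq$nodes[length(sq$nodes)] == u, valid)
    if (length(vu) == 0) next
    lens <- vapply(vu, function(sq) sum(sq$hop), numeric(1))
    if (spatialTiebreak) {
      best <- min(lens)
      opt <- vu[lens <= best + 1e-9 * max(1, best)]
      sdist[u] <- best
    } else {
      opt <- vu
      sdist[u] <- min(lens)
    }
    sigma[u] <- length(opt)
    ints <- unlist(lapply(opt, function(sq) {
      nd <- sq$nodes
      if (length(nd) > 2) nd[-c(1, length(nd))] else integer(0)
    }))
    interior[[u]] <- list(counts = table(factor(
      unlist(lapply(opt, function(sq) {
        nd <- sq$nodes
        unique(if (length(nd) > 2) nd[-c(1, length(nd))] else integer(0))
      })), levels = seq_len(n))), members = unique(ints))
  }
  list(arr = earliest, sdist = sdist, sigma = sigma, interior = interior)
}

# Full oracle analysis: distance/count matrices plus PB/BE scores.
oracleAnalysis <- function(net, window = NULL, spatialTiebreak = TRUE) {
  n <- nNodes(net)
  arr <- sdist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  pb <- be <- numeric(n)
  for (v0 in seq_len(n)) {
    o <- oracleOrigin(net, v0, window, spatialTiebreak)
    arr[v0, ] <- o$arr
    sdist[v0, ] <- o$sdist
    sigma[v0, ] <- o$sigma
    for (u in seq_len(n)) {
      if (u == v0 || is.null(o$interior[[u]])) next
      cnt <- o$interior[[u]]$counts  # optimal paths containing x (interior)
      pb <- pb + as.numeric(cnt) / o$sigma[u]
      mem <- o$interior[[u]]$members
      if (length(mem)) be[mem] <- be[mem] + 1 / o$arr[u]
    }
  }
  list(latSteps = arr, sdist = sdist, sigma = sigma, reach = is.finite(arr),
       pb = pb, be = be)
}
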