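test_that("single-step progress accumulates tau * speed, capped at the gap", {
  city <- twoCityFixture()
  st <- initPropagation(city, "v")
  st <- propagationStep(st, city, 2)
  expect_equal(st@P[1, 2], 50)          # 900 s at 200 km/h = 50 km
  expect_true(is.na(st@arrival[2]))
  st <- propagationStep(st, city, 3)
  expect_equal(st@P[1, 2], 100)
  st <- propagationStep(st, city, 4)
  expect_equal(st@P[1, 2], 150)
  expect_equal(st@arrival[2], 4L)       # three elapsed timesteps
})

test_that("progress resets to zero when the carrying edge disappears", {
  f1 <- fiveNodeFixture()
  res <- runPropagation(f1, "A", trace = TRUE)
  Pseq <- vapply(res$trace, function(st) st@P["A", "D"], numeric(1))
  # A->D: accumulates at t2, resets at t3, re-accumulates t4-t5, resets t6
  expect_equal(Pseq, c(0, 1, 0, 1, 2, 0), ignore_attr = TRUE)
  expect_true(is.na(res$summary@arrival["D"]))
})

test_that("infinite-speed edges complete in the first step they appear", {
  net <- mkNet(c("a", "b"),
               data.frame(t = 3, source = "a", target = "b", speed = Inf),
               nSteps = 4, positions = rbind(c(0, 0), c(500, 0)))
  s <- runPropagation(net, "a")
  expect_equal(unname(s@arrival["b"]), 3L)
  expect_equal(unname(s@sdist["b"]), 500)
})

test_that("figure-style worked example yields the printed path to E", {
  f1 <- fiveNodeFixture()
  s <- runPropagation(f1, "A")
  expect_equal(unname(s@latency["E"]), 5)   # seconds
  expect_equal(unname(s@sdist["E"]), 4)     # metres, via B and C
  expect_equal(unname(s@arrival[c("B", "C")]), c(2L, 4L))
  expect_false(is.finite(s@latency["D"]))
  expect_false(is.finite(s@sdist["D"]))     # both distances infinite together
})

test_that("R-level stepping reproduces the compiled engine trace", {
  for (seed in c(3, 14, 27)) {
    net <- smallRandomNet(seed)
    origin <- nodeIds(net)[1]
    res <- runPropagation(net, origin, trace = TRUE)
    st <- initPropagation(net, origin)
    for (i in 2:nSnapshots(net)) {
      st <- propagationStep(st, net, i)
      expect_equal(st@P, res$trace[[i]]@P, tolerance = 1e-12)
      expect_identical(is.na(st@arrival), is.na(res$trace[[i]]@arrival))
    }
    expect_equal(st@arrival, unname(res$summary@arrival))
  }
})

test_that("a window of length one reaches nothing beyond the origin", {
  net <- smallRandomNet(5)
  s <- runPropagation(net, nodeIds(net)[2], window = c(1, 1))
  expect_equal(sum(is.finite(s@latency)), 1)
  expect_equal(unname(s@latency[2]), 0)
})

test_that("reachability sets grow monotonically along every trace", {
  for (seed in 1:5) {
    net <- smallRandomNet(seed)
    for (origin in nodeIds(net)) {
      res <- runPropagation(net, origin, trace = TRUE)
      sizes <- vapply(res$trace, function(st) sum(!is.na(st@arrival)),
                      numeric(1))
      expect_true(all(diff(sizes) >= 0))
      expect_true(all(vapply(res$trace, function(st)
        !is.na(st@arrival[match(origin, nodeIds(net))]), logical(1))))
    }
  }
})

test_that("emitted paths respect strict temporal ordering", {
  extractPath <- function(summ, w) {
    # walk one shortest path backwards through the DAG
    path <- w
    while (path[1] != match(summ@origin, summ@nodes)) {
      p <- summ@dag[[path[1]]][1]
      path <- c(p, path)
    }
    path
  }
  for (seed in c(2, 9)) {
    net <- smallRandomNet(seed)
    for (origin in nodeIds(net)) {
      s <- runPropagation(net, origin)
      for (w in which(is.finite(s@latency))) {
        path <- extractPath(s, w)
        arr <- s@arrival[path]
        expect_true(all(diff(arr) > 0) || length(path) == 1)
        expect_equal(anyDuplicated(path), 0)
      }
    }
  }
})

test_that("spatial distance respects the straight-line lower bound", {
  # static positions: a path's spatial length cannot undercut the metric
  for (seed in c(4, 21)) {
    net <- smallRandomNet(seed)
    ap <- allPairs(net)
    D <- distanceMatrix(net, 1)
    fin <- is.finite(ap$sdist) & row(D) != col(D)
    expect_true(all(ap$sdist[fin] >= D[fin] - 1e-9))
  }
})

test_that("all-pairs results are independent of origin execution order", {
  net <- smallRandomNet(8)
  ap1 <- allPairs(net, centrality = TRUE)
  ap2 <- allPairs(net, centrality = TRUE)  # recompute: bit-identical
  expect_identical(ap1$latSteps, ap2$latSteps)
  expect_identical(ap1$sdist, ap2$sdist)
  expect_identical(ap1$pb, ap2$pb)
  # per-origin runs agree with the all-pairs sweep row by row
  for (origin in sample(nodeIds(net))) {
    s <- runPropagation(net, origin)
    expect_equal(ap1$latency[origin, ], s@latency)
    expect_equal(ap1$sdist[origin, ], s@sdist)
  }
})

test_that("parallel origin sweeps reproduce the serial results", {
  net <- smallRandomNet(13)
  serial <- allPairs(net, centrality = TRUE)
  par2 <- allPairs(net, centrality = TRUE, jobs = 2L)
  expect_identical(serial$latSteps, par2$latSteps)
  expect_identical(serial$sdist, par2$sdist)
  expect_identical(serial$pb, par2$pb)
})

test_that("all-pairs one-step network has uniform latency tau", {
  net <- completeOneStepNet(4)
  ap <- allPairs(net)
  off <- ap$latSteps[row(ap$latSteps) != col(ap$latSteps)]
  expect_true(all(off == 1))
  expect_true(all(diag(ap$latSteps) == 0))
  expect_true(all(ap$reach))
})

test_that("horizon growth is non-decreasing and plateaus in service gaps", {
  # two line segments sharing station C; the outer segment only enters
  # service at step 9, so S plateaus while no service runs
  bidir <- function(t, a, b) data.frame(t = t, source = c(a, b),
                                        target = c(b, a), speed = 1)
  edges <- rbind(
    do.call(rbind, lapply(1:4, function(t) rbind(bidir(t, "A", "B"),
                                                 bidir(t, "B", "C")))),
    do.call(rbind, lapply(9:12, function(t) rbind(bidir(t, "C", "D"),
                                                  bidir(t, "D", "E"),
                                                  bidir(t, "E", "F")))))
  net <- mkNet(LETTERS[1:6], edges, nSteps = 12)
  hg <- horizonGrowth(net, c(1, 2, 4, 5, 6, 7, 8, 9, 10, 11, 12))
  expect_true(all(diff(hg$S) >= 0))
  expect_equal(hg$S[1], 1 / 6)             # h = tau: singleton components
  expect_equal(hg$S[hg$h == 4], 3 / 6)     # A, B, C mutually reachable
  gap <- hg$h >= 4 & hg$h <= 10            # outer segment not yet mutual
  expect_equal(unique(hg$S[gap]), 3 / 6)
  expect_equal(hg$S[hg$h == 12], 4 / 6)    # C, D, E, F; no path back to A, B
  expect_error(horizonGrowth(net, numeric(0)), "empty")
})
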