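namedGraph <- function(g, prefix = "v") {
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(igraph::vcount(g)))
  g
}

test_that("node weight matches closed forms on stars, cliques and isolates", {
  star <- namedGraph(igraph::make_star(5, mode = "undirected"))
  w <- nodeWeights(star)
  expect_equal(unname(w["v01"]), 1)            # center sees 4 leaves of degree 1
  expect_equal(unname(w["v03"]), 4)            # each leaf sees the center
  expect_equal(nodeWeight(star, "v02"), 4)

  tri <- namedGraph(igraph::make_full_graph(3))
  expect_equal(unname(nodeWeights(tri)), rep(2, 3))  # k-regular -> weight k

  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "solo"
  expect_equal(unname(nodeWeights(iso)), 0)
  expect_error(nodeWeight(tri, "nope"), "not in network")
})

test_that("induced-subgraph node weight context is confined to the neighbourhood", {
  # path a-b-c: in full-network context w(b) = mean(deg a, deg c) = 1;
  # induced on {a,b,c} it is the same; but for the star center the induced
  # subgraph is the star itself while each leaf's induced subgraph is one edge
  star <- namedGraph(igraph::make_star(5, mode = "undirected"))
  wInd <- nodeWeights(star, context = "induced")
  expect_equal(unname(wInd["v01"]), 1)  # leaves have degree 1 in the star
  expect_equal(unname(wInd["v02"]), 1)  # center has degree 1 in the pair subgraph
})

test_that("edge weight matches closed forms and stays in [0, 1)", {
  tri <- namedGraph(igraph::make_full_graph(3))
  expect_equal(edgeWeight(tri, "v01", "v02"), 1 / 3)

  pair <- namedGraph(igraph::make_full_graph(2))
  expect_equal(edgeWeight(pair, "v01", "v02"), 0)

  k4 <- namedGraph(igraph::make_full_graph(4))
  expect_equal(edgeWeight(k4, "v01", "v02"), 0.5)
  expect_error(edgeWeight(k4, "v01", "zz"), "not in network")

  path <- namedGraph(igraph::make_ring(4, circular = FALSE))
  expect_error(edgeWeight(path, "v01", "v04"), "edge not in network")

  case <- randomGraphCase(40, 0.15, seed = 3)
  w <- edgeWeights(case$g)
  expect_true(all(w >= 0 & w < 1))
})

test_that("cutoff threshold reproduces the worked example and its properties", {
  v <- c(0, 1, 2, 3)
  # independent arithmetic: alpha 1.5, population variance 1.25
  expect_equal(cutoffThreshold(v, "low"),
               1.5 + 1 * sqrt(1.25) * (1 - 1 / 2.25), tolerance = 1e-12)
  expect_equal(cutoffThreshold(v, 2), 1.5 + 2 * sqrt(1.25) * (1 - 1 / 2.25))
  expect_equal(cutoffThreshold(v, "high"), 1.5 + 3 * sqrt(1.25) * (1 - 1 / 2.25))

  # equal values collapse to the mean at every level
  expect_equal(cutoffThreshold(rep(7, 5), 1), 7)
  expect_equal(cutoffThreshold(rep(7, 5), 3), 7)

  # monotone in k, strictly so when the spread is positive
  set.seed(1)
  for (i in 1:20) {
    vals <- stats::runif(sample(2:30, 1), 0, 10)
    th <- vapply(1:3, function(k) cutoffThreshold(vals, k), numeric(1))
    expect_true(all(diff(th) > 0))
    expect_true(th[1] > mean(vals))
  }

  expect_error(cutoffThreshold(numeric(0), 1), "no values")
  expect_error(cutoffThreshold(1:3, 4), "level")

  # sample-sd switch is larger than population-sd for the same data
  expect_gt(cutoffThreshold(v, 1, sd = "sample"), cutoffThreshold(v, 1))
})

test_that("regular graphs survive node pruning unchanged (sigma = 0)", {
  ring <- namedGraph(igraph::make_ring(8))
  for (lev in c("low", "medium", "high")) {
    out <- pruneNodes(ring, lev)
    expect_equal(igraph::vcount(out), 8)
    expect_equal(igraph::ecount(out), 8)
  }
  # clique edges all tie as well: edge stage removes nothing
  k5 <- namedGraph(igraph::make_full_graph(5))
  out <- pruneEdges(k5, "high")
  expect_equal(igraph::ecount(out), 10)
})

test_that("node pruning equals the brute-force snapshot filter", {
  for (seed in 1:12) {
    case <- randomGraphCase(sample(10:40, 1), 0.15, seed = seed)
    for (k in 1:3) {
      survivors <- bfPruneNodesSurvivors(case$el, case$nodes, k)
      got <- pruneNodes(case$g, k)
      expect_setequal(igraph::V(got)$name, survivors)
    }
  }
})

test_that("edge pruning filters edges then drops stranded nodes", {
  for (seed in 1:8) {
    case <- randomGraphCase(sample(10:35, 1), 0.2, seed = 100 + seed)
    if (nrow(case$el) < 2) next
    w <- vapply(seq_len(nrow(case$el)), function(i)
      bfEdgeWeight(case$el, case$el[i, 1], case$el[i, 2]), numeric(1))
    for (k in 1:3) {
      keep <- w >= bfTheta(w, k)
      kept <- case$el[keep, , drop = FALSE]
      got <- pruneEdges(case$g, k)
      expect_equal(igraph::ecount(got), sum(keep))
      expect_setequal(igraph::V(got)$name, unique(as.vector(kept)))
    }
  }
  # edgeless network: unchanged with a warning
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("a", "b", "c")
  expect_warning(out <- pruneEdges(lone, 1), "no edges")
  expect_equal(igraph::vcount(out), 3)
})

test_that("two-stage pruning reports exactly what it returns", {
  for (seed in c(2, 21)) {
    bench <- generateBenchmark(syntheticSpec(seed = seed))
    for (lev in c("low", "medium", "high")) {
      pr <- pruneNetwork(bench$network, lev)
      rep <- pr$report
      expect_s4_class(rep, "PruningReport")
      expect_equal(rep@nodesInitial, igraph::vcount(bench$network))
      expect_equal(rep@edgesInitial, igraph::ecount(bench$network))
      expect_equal(rep@nodesAfterEdgeReduction, igraph::vcount(pr$network))
      expect_equal(rep@edgesAfterEdgeReduction, igraph::ecount(pr$network))
      # stagewise recount
      g1 <- pruneNodes(bench$network, lev)
      expect_equal(rep@nodesAfterNodeReduction, igraph::vcount(g1))
      expect_equal(rep@edgesAfterNodeReduction, igraph::ecount(g1))
      expect_equal(rep@nodeThreshold, attr(g1, "threshold"))
      # pruned network is a subgraph of the input
      expect_true(all(igraph::V(pr$network)$name %in%
                        igraph::V(bench$network)$name))
    }
  }
})

test_that("node-stage survivors are nested across cut-off levels", {
  for (seed in c(4, 13, 31)) {
    case <- randomGraphCase(45, 0.15, seed = seed)
    sLow <- igraph::V(pruneNodes(case$g, "low"))$name
    sMed <- igraph::V(pruneNodes(case$g, "medium"))$name
    sHigh <- igraph::V(pruneNodes(case$g, "high"))$name
    expect_true(all(sHigh %in% sMed))
    expect_true(all(sMed %in% sLow))
  }
})
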