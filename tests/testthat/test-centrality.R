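namedGraph <- function(g, prefix = "v") {
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(igraph::vcount(g)))
  g
}

test_that("LID matches closed forms on canonical neighbourhoods", {
  star <- namedGraph(igraph::make_star(6, mode = "undirected"))
  expect_equal(lid(star, "v01"), 0)  # pairwise non-adjacent neighbours

  tri <- namedGraph(igraph::make_full_graph(3))
  expect_equal(lid(tri, "v01"), 0.5)  # 1 edge between 2 interconnected neighbours

  k4 <- namedGraph(igraph::make_full_graph(4))
  expect_equal(lid(k4, "v02"), 1)     # 3 edges among 3 neighbours

  expect_error(lid(k4, "nope"), "not in network")
})

test_that("LID denominator counts only interconnected neighbours", {
  # u adjacent to a, b, c, d; only a-b adjacent among them:
  # E(u) = 1, V(u) = {a, b} -> 0.5 (not 1/4)
  g <- igraph::graph_from_edgelist(
    cbind(c("u", "u", "u", "u", "a"), c("a", "b", "c", "d", "b")),
    directed = FALSE)
  expect_equal(lid(g, "u"), 0.5)
})

test_that("LID respects the clique bound (deg - 1) / 2", {
  for (seed in 1:10) {
    case <- randomGraphCase(30, 0.2, seed = 200 + seed)
    l <- lidScores(case$g)
    d <- degreeCentrality(case$g)
    expect_true(all(l <= pmax(0, (d - 1) / 2) + 1e-12))
  }
  k6 <- namedGraph(igraph::make_full_graph(6))
  expect_equal(unname(lidScores(k6)), rep((6 - 2) / 2, 6))  # equality on cliques
})

test_that("IDC counts complex co-member interactions per complex", {
  g <- igraph::graph_from_edgelist(cbind(c("a", "a"), c("b", "c")),
                                   directed = FALSE)
  expect_equal(unname(idc(g, ComplexCatalog(list()), "a")), 0)
  catNoEdge <- ComplexCatalog(list(c("a", "x", "y")))
  expect_equal(unname(idc(g, catNoEdge, "a")), 0)

  cat1 <- ComplexCatalog(list(c("a", "b", "c")))
  expect_equal(unname(idc(g, cat1, "a")), 2)
  # a second complex recounts the shared co-member
  cat2 <- ComplexCatalog(list(c("a", "b", "c"), c("a", "b")))
  expect_equal(unname(idc(g, cat2, "a")), 3)
  expect_equal(unname(idc(g, cat2, "b")), 2)
  expect_equal(unname(idc(g, cat2, "c")), 1)
})

test_that("IDC and LID equal brute-force enumeration on random graphs", {
  for (seed in 1:10) {
    case <- randomGraphCase(sample(8:30, 1), 0.25, seed = 300 + seed)
    cat <- randomCatalogCase(case$nodes, 4, seed = 300 + seed)
    l <- lidScores(case$g)
    d <- idcScores(case$g, cat)
    for (u in sample(case$nodes, 6)) {
      expect_equal(unname(l[u]), bfLID(case$el, u))
      expect_equal(unname(d[u]), bfIDC(case$el, complexes(cat), u, case$nodes))
    }
  }
})

test_that("ranking by LID is descending with identifier tie-break", {
  # all-equal LID: ranks follow identifier order
  k4 <- namedGraph(igraph::make_full_graph(4))
  r <- rankByLID(k4)
  expect_identical(unname(r[sprintf("v%02d", 1:4)]), 1:4)

  for (seed in 1:8) {
    case <- randomGraphCase(25, 0.2, seed = 400 + seed)
    r <- rankByLID(case$g)
    expect_setequal(unname(r), seq_along(case$nodes))
    expect_identical(unname(r), unname(bfRankByLID(case$el, case$nodes)))
    l <- lidScores(case$g)
    expect_equal(unname(r[names(which.max(l))]), 1)  # rank 1 holds max LID
  }
})

test_that("LIDC is the rank-weighted convex combination of LID and IDC", {
  for (seed in 1:8) {
    case <- randomGraphCase(20, 0.25, seed = 500 + seed)
    cat <- randomCatalogCase(case$nodes, 3, seed = 500 + seed)
    st <- lidcScores(case$g, cat)
    df <- scores(st)
    n <- nrow(df)
    expect_equal(df$lidc,
                 df$lid * (1 - df$rank / n) + df$idc * df$rank / n)
    expect_true(all(df$lidc >= pmin(df$lid, df$idc) - 1e-12))
    expect_true(all(df$lidc <= pmax(df$lid, df$idc) + 1e-12))
  }
})

test_that("rank N and single-node networks reduce LIDC to IDC", {
  # single node: N = 1, rank = 1, lidc = idc
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "a"
  st <- lidcScores(g1, ComplexCatalog(list(c("a", "b"))))
  expect_equal(scores(st)$lidc, scores(st)$idc)

  # the protein ranked N has weight fully on IDC
  case <- randomGraphCase(15, 0.3, seed = 77)
  cat <- randomCatalogCase(case$nodes, 3, seed = 77)
  df <- scores(lidcScores(case$g, cat))
  last <- df[df$rank == nrow(df), ]
  expect_equal(last$lidc, as.numeric(last$idc))
})

test_that("with an empty catalog LIDC is LID reweighted by rank", {
  case <- randomGraphCase(18, 0.3, seed = 88)
  df <- scores(lidcScores(case$g, ComplexCatalog()))
  expect_true(all(df$idc == 0))
  expect_equal(df$lidc, df$lid * (1 - df$rank / nrow(df)))
})

test_that("scores are invariant to node and edge input order", {
  case <- randomGraphCase(22, 0.25, seed = 99)
  cat <- randomCatalogCase(case$nodes, 3, seed = 99)
  perm <- igraph::permute(case$g, sample(igraph::vcount(case$g)))
  expect_equal(scores(lidcScores(perm, cat)), scores(lidcScores(case$g, cat)))
  expect_equal(nodeWeights(perm)[case$nodes], nodeWeights(case$g)[case$nodes])
})

test_that("degree centrality matches edge incidence", {
  star <- namedGraph(igraph::make_star(5, mode = "undirected"))
  dc <- degreeCentrality(star)
  expect_equal(unname(dc["v01"]), 4L)
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "x"
  expect_equal(unname(degreeCentrality(iso)), 0L)
  case <- randomGraphCase(25, 0.2, seed = 123)
  dc <- degreeCentrality(case$g)
  for (u in sample(case$nodes, 5))
    expect_equal(unname(dc[u]), bfDegree(case$el, u))
})

test_that("planted-module members outscore the background on average", {
  for (seed in c(6, 16)) {
    bench <- generateBenchmark(syntheticSpec(seed = seed))
    st <- lidcScores(bench$network, bench$catalog)
    df <- scores(st)
    inMod <- df$protein %in% bench$truth@moduleMembers
    expect_gt(mean(df$lidc[inMod]), mean(df$lidc[!inMod]))
  }
})
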