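# Independent brute-force oracles. Everything here works on a plain
# two-column character edge matrix with base-R set arithmetic, deliberately
# sharing no code path with the package implementation.

bfNeighbors <- function(el, v) {
  unique(c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))
}

bfDegree <- function(el, v) length(bfNeighbors(el, v))

bfAdjacent <- function(el, a, b) {
  any((el[, 1] == a & el[, 2] == b) | (el[, 1] == b & el[, 2] == a))
}

bfNodeWeight <- function(el, v) {
  nb <- bfNeighbors(el, v)
  if (length(nb) == 0L) return(0)
  mean(vapply(nb, function(u) bfDegree(el, u), numeric(1)))
}

bfEdgeWeight <- function(el, u, v) {
  nu <- bfNeighbors(el, u); nv <- bfNeighbors(el, v)
  length(intersect(nu, nv)) / length(union(nu, nv))
}

bfLID <- function(el, u) {
  nb <- bfNeighbors(el, u)
  if (length(nb) < 2L) return(0)
  nEdges <- 0L
  connected <- character(0)
  for (i in seq_len(length(nb) - 1L)) {
    for (j in (i + 1L):length(nb)) {
      if (bfAdjacent(el, nb[i], nb[j])) {
        nEdges <- nEdges + 1L
        connected <- union(connected, c(nb[i], nb[j]))
      }
    }
  }
  if (nEdges == 0L) 0 else nEdges / length(connected)
}

bfIDC <- function(el, cxList, u, nodes) {
  total <- 0L
  for (members in cxList) {
    if (!u %in% members) next
    for (m in setdiff(intersect(members, nodes), u))
      if (bfAdjacent(el, u, m)) total <- total + 1L
  }
  total
}

bfTheta <- function(values, k) {
  a <- mean(values)
  s2 <- mean((values - a)^2)
  a + k * sqrt(s2) * (1 - 1 / (1 + s2))
}

# stable descending-LID rank with ascending-identifier tie-break
bfRankByLID <- function(el, nodes) {
  lids <- vapply(nodes, function(u) bfLID(el, u), numeric(1))
  ord <- nodes[order(-lids, nodes)]
  stats::setNames(match(nodes, ord), nodes)
}

bfPruneNodesSurvivors <- function(el, nodes, k) {
  w <- vapply(nodes, function(v) bfNodeWeight(el, v), numeric(1))
  nodes[w >= bfTheta(w, k)]
}

# random simple graph fixture: igraph object + its edge matrix + node ids
randomGraphCase <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  el <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(el) > 0L)
    g <- igraph::add_edges(g, t(matrix(match(el, ids), ncol = 2)))
  list(g = g, el = el, nodes = ids)
}

# random complex catalog over the given nodes
randomCatalogCase <- function(nodes, nComplexes, seed) {
  set.seed(seed)
  cx <- lapply(seq_len(nComplexes), function(i)
    sample(nodes, min(length(nodes), sample(2:6, 1L))))
  ComplexCatalog(cx)
}
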