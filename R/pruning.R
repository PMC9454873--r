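#' Cut-off levels
#'
#' The pruning threshold is applied at three stringency levels; `k` = 1, 2, 3
#' correspond to low, medium and high.
#'
#' @param level `"low"`, `"medium"`, `"high"` (or 1, 2, 3).
#' @return Integer k in 1..3.
#' @keywords internal
cutoffK <- function(level) {
  if (is.numeric(level)) {
    k <- as.integer(level)
    if (!k %in% 1:3) stop("cut-off level must be in {1, 2, 3}")
    return(k)
  }
  k <- match(match.arg(level, c("low", "medium", "high")),
             c("low", "medium", "high"))
  k
}

levelName <- function(level) c("low", "medium", "high")[cutoffK(level)]

#' Node weights: average neighbour degree
#'
#' The weight of a node v is the mean degree of its neighbours, a proxy for
#' how well-connected v's neighbourhood is. Neighbourhoods are open (v is not
#' its own neighbour). By default degrees are taken in the full network passed
#' in; `context = "induced"` instead takes them in the subgraph induced by
#' the closed neighbourhood of v (a stricter, locally-confined variant).
#' A degree-0 node has weight 0 by convention.
#'
#' @param network An undirected simple [igraph::igraph].
#' @param context `"network"` (default) or `"induced"`.
#' @return Named numeric vector of weights, one per node.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")  # center + 4 leaves
#' nodeWeights(g)  # center 1, leaves 4
#' @export
nodeWeights <- function(network, context = c("network", "induced")) {
  context <- match.arg(context)
  nodes <- igraph::V(network)$name
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  if (context == "network") {
    deg <- igraph::degree(network)
    w <- vapply(adj, function(nb)
      if (length(nb) == 0L) 0 else mean(deg[as.integer(nb)]), numeric(1))
  } else {
    w <- vapply(seq_along(nodes), function(i) {
      nb <- as.integer(adj[[i]])
      if (length(nb) == 0L) return(0)
      sub <- igraph::induced_subgraph(network, c(i, nb))
      degs <- igraph::degree(sub)
      mean(degs[igraph::V(sub)$name != nodes[i]])
    }, numeric(1))
  }
  stats::setNames(w, nodes)
}

#' Node weight of a single protein
#'
#' @param network An undirected simple [igraph::igraph].
#' @param v A protein identifier present in the network.
#' @inheritParams nodeWeights
#' @return The node weight of `v`.
#' @export
nodeWeight <- function(network, v, context = c("network", "induced")) {
  if (!v %in% igraph::V(network)$name)
    stop("protein not in network: ", v)
  unname(nodeWeights(network, context)[v])
}

#' Edge weights: neighbourhood overlap
#'
#' The weight of an edge u-v is the Jaccard-style overlap of the two open
#' neighbourhoods, |Gamma(u) n Gamma(v)| / |Gamma(u) u Gamma(v)| — the ratio
#' of common to distinct neighbours — used as a proxy for interaction
#' reliability. For an existing edge the union always contains both u and v,
#' so the value lies in [0, 1).
#'
#' @param network An undirected simple [igraph::igraph] with at least 1 edge.
#' @return Numeric vector, one weight per edge in igraph edge order.
#' @export
edgeWeights <- function(network) {
  el <- igraph::as_edgelist(network, names = FALSE)
  if (nrow(el) == 0L) return(numeric(0))
  adj <- lapply(igraph::adjacent_vertices(network, igraph::V(network)),
                as.integer)
  vapply(seq_len(nrow(el)), function(i) {
    nu <- adj[[el[i, 1L]]]; nv <- adj[[el[i, 2L]]]
    common <- length(intersect(nu, nv))
    common / (length(nu) + length(nv) - common)
  }, numeric(1))
}

#' Edge weight of a single interaction
#'
#' @param network An undirected simple [igraph::igraph].
#' @param u,v Protein identifiers joined by an edge.
#' @return The edge weight of u-v.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' edgeWeight(g, "a", "b")  # 1/3
#' @export
edgeWeight <- function(network, u, v) {
  names <- igraph::V(network)$name
  if (!u %in% names || !v %in% names)
    stop("protein not in network")
  eid <- igraph::get_edge_ids(network, c(u, v))
  if (eid == 0L) stop("edge not in network: ", u, "-", v)
  nu <- names[as.integer(igraph::adjacent_vertices(network, u)[[1]])]
  nv <- names[as.integer(igraph::adjacent_vertices(network, v)[[1]])]
  length(intersect(nu, nv)) / length(union(nu, nv))
}

#' Pruning cut-off threshold
#'
#' theta_k = alpha + k * sigma * (1 - 1 / (1 + sigma^2)), where alpha is the
#' mean and sigma the standard deviation of the weight values and k in
#' {1, 2, 3} selects the low / medium / high cut-off. sigma is the population
#' standard deviation by default (`sd = "sample"` divides by n - 1 instead).
#' When all values are equal, sigma = 0 and theta_k collapses to alpha for
#' every k.
#'
#' @param values Non-empty numeric vector of node or edge weights.
#' @param level Cut-off level: `"low"`, `"medium"`, `"high"` or 1..3.
#' @param sd `"population"` (default) or `"sample"`.
#' @return The threshold theta_k.
#' @examples
#' cutoffThreshold(c(0, 1, 2, 3), "low")  # ~2.1211
#' @export
cutoffThreshold <- function(values, level, sd = c("population", "sample")) {
  if (length(values) == 0L) stop("cannot compute a cut-off from no values")
  sd <- match.arg(sd)
  k <- cutoffK(level)
  alpha <- mean(values)
  n <- length(values)
  sig2 <- sum((values - alpha)^2) / if (sd == "population") n else max(n - 1L, 1L)
  sig <- sqrt(sig2)
  alpha + k * sig * (1 - 1 / (1 + sig2))
}

#' Node-weight pruning stage
#'
#' Removes every node whose weight falls strictly below theta_k, together with
#' its incident edges. Snapshot semantics: all weights are computed on the
#' input network and the threshold on those weights; there is no recomputation
#' between removals. Nodes whose weight equals the threshold survive.
#'
#' @inheritParams nodeWeights
#' @param level Cut-off level (`"low"`, `"medium"`, `"high"` or 1..3).
#' @param sd Passed to [cutoffThreshold()].
#' @return The node-reduced network, with attribute `threshold`.
#' @export
pruneNodes <- function(network, level, context = c("network", "induced"),
                       sd = c("population", "sample")) {
  if (igraph::vcount(network) == 0L) stop("network is empty")
  w <- nodeWeights(network, context)
  theta <- cutoffThreshold(w, level, sd)
  out <- igraph::delete_vertices(network, names(w)[w < theta])
  attr(out, "threshold") <- theta
  out
}

#' Edge-weight pruning stage
#'
#' Removes every edge whose weight falls strictly below theta_k (weights and
#' threshold computed on the input network, snapshot semantics), then drops
#' nodes stranded at degree 0: a protein left without any reliable interaction
#' carries no signal for the density-based scores of phase two.
#'
#' @inheritParams pruneNodes
#' @return The edge-reduced network, with attribute `threshold`.
#' @export
pruneEdges <- function(network, level, sd = c("population", "sample")) {
  if (igraph::ecount(network) == 0L) {
    warning("network has no edges; returned unchanged")
    attr(network, "threshold") <- NA_real_
    return(network)
  }
  w <- edgeWeights(network)
  theta <- cutoffThreshold(w, level, sd)
  out <- igraph::delete_edges(network, which(w < theta))
  out <- igraph::delete_vertices(out, which(igraph::degree(out) == 0L))
  attr(out, "threshold") <- theta
  out
}

#' Two-stage network pruning
#'
#' Phase one of the pipeline: node-weight pruning followed by edge-weight
#' pruning at the same cut-off level, with a report of the network statistics
#' at each stage.
#'
#' @inheritParams pruneNodes
#' @return A list with elements `network` (the pruned [igraph::igraph]) and
#'   `report` (a [PruningReport-class]).
#' @examples
#' g <- igraph::sample_gnp(40, 0.2)
#' igraph::V(g)$name <- sprintf("P%03d", 1:40)
#' pr <- pruneNetwork(g, "high")
#' pr$report
#' @export
pruneNetwork <- function(network, level, context = c("network", "induced"),
                         sd = c("population", "sample")) {
  n0 <- igraph::vcount(network); e0 <- igraph::ecount(network)
  g1 <- pruneNodes(network, level, context, sd)
  thN <- attr(g1, "threshold")
  if (igraph::ecount(g1) > 0L) {
    g2 <- pruneEdges(g1, level, sd)
    thE <- attr(g2, "threshold")
  } else {
    g2 <- igraph::delete_vertices(g1, seq_len(igraph::vcount(g1)))
    thE <- NA_real_
  }
  report <- new("PruningReport", level = levelName(level),
                nodesInitial = as.integer(n0), edgesInitial = as.integer(e0),
                nodesAfterNodeReduction = as.integer(igraph::vcount(g1)),
                edgesAfterNodeReduction = as.integer(igraph::ecount(g1)),
                nodesAfterEdgeReduction = as.integer(igraph::vcount(g2)),
                edgesAfterEdgeReduction = as.integer(igraph::ecount(g2)),
                nodeThreshold = thN, edgeThreshold = thE)
  list(network = g2, report = report)
}
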