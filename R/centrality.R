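#' Local interaction density (LID)
#'
#' LID(u) = |E(u)| / |V(u)|, where E(u) is the set of edges among u's
#' neighbours and V(u) the set of neighbours of u that are connected to at
#' least one other neighbour of u ("interconnected neighbours"). A node whose
#' neighbours are pairwise non-adjacent has LID 0 (the 0/0 convention).
#' For a member of a clique LID attains its upper bound (deg(u) - 1) / 2.
#'
#' @param network An undirected simple [igraph::igraph].
#' @return Named numeric vector of LID values.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' lidScores(g)  # all 1: 3 edges among 3 interconnected neighbours
#' @export
lidScores <- function(network) {
  nodes <- igraph::V(network)$name
  adj <- lapply(igraph::adjacent_vertices(network, igraph::V(network)),
                as.integer)
  w <- vapply(seq_along(nodes), function(i) {
    nb <- adj[[i]]
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(network, nb)
    ne <- igraph::ecount(sub)
    if (ne == 0L) return(0)
    nv <- sum(igraph::degree(sub) > 0L)
    ne / nv
  }, numeric(1))
  stats::setNames(w, nodes)
}

#' LID of a single protein
#'
#' @inheritParams lidScores
#' @param u A protein identifier present in the network.
#' @return The LID of `u`.
#' @export
lid <- function(network, u) {
  if (!u %in% igraph::V(network)$name) stop("protein not in network: ", u)
  unname(lidScores(network)[u])
}

#' In-degree centrality of complex (IDC)
#'
#' IDC(u) sums, over every complex that contains u, the number of network
#' edges between u and the other members of that complex. A protein in no
#' complex scores 0; co-members absent from the network contribute nothing;
#' a co-member shared by two complexes is counted once per complex. Edges are
#' taken from the network passed in — in the pipeline this is the pruned
#' network, since phase two runs entirely on it.
#'
#' @param network An undirected simple [igraph::igraph].
#' @param catalog A [ComplexCatalog-class].
#' @return Named integer vector of IDC values.
#' @export
idcScores <- function(network, catalog) {
  nodes <- igraph::V(network)$name
  score <- stats::setNames(integer(length(nodes)), nodes)
  adjNames <- lapply(igraph::adjacent_vertices(network, igraph::V(network)),
                     function(nb) nodes[as.integer(nb)])
  names(adjNames) <- nodes
  for (members in complexes(catalog)) {
    inNet <- intersect(members, nodes)
    for (u in inNet) {
      score[u] <- score[u] + sum(adjNames[[u]] %in% setdiff(members, u))
    }
  }
  score
}

#' IDC of a single protein
#'
#' @inheritParams idcScores
#' @param u A protein identifier present in the network.
#' @return The IDC of `u` (non-negative integer).
#' @export
idc <- function(network, catalog, u) {
  if (!u %in% igraph::V(network)$name) stop("protein not in network: ", u)
  unname(idcScores(network, catalog)[u])
}

#' Rank proteins by descending LID
#'
#' 1-based ranks from a descending sort of LID; ties are broken by ascending
#' protein identifier so the ranking is deterministic.
#'
#' @inheritParams lidScores
#' @return Named integer vector mapping each protein to its rank in 1..N.
#' @export
rankByLID <- function(network) {
  if (igraph::vcount(network) == 0L) stop("network is empty")
  l <- lidScores(network)
  ord <- order(-l, names(l))
  stats::setNames(order(ord), names(l))[names(l)]
}

#' LIDC scores: rank-weighted combination of LID and IDC
#'
#' LIDC(u) = LID(u) * (1 - RANK(u)/N) + IDC(u) * RANK(u)/N, where RANK(u) is
#' u's position in the descending LID ordering and N the number of proteins
#' in the network being scored. A protein ranked high by LID keeps mostly its
#' LID; a protein ranked low is scored mostly by its complex in-degree. LIDC
#' is therefore a convex combination, bounded by min and max of (LID, IDC)
#' per protein. The final ordering is descending LIDC with ties broken by
#' ascending identifier.
#'
#' @inheritParams idcScores
#' @return A [ScoreTable-class] ordered by the final ranking.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' lidcScores(g, ComplexCatalog(list(c("a", "b"))))
#' @export
lidcScores <- function(network, catalog = ComplexCatalog()) {
  if (igraph::vcount(network) == 0L) stop("network is empty")
  l <- lidScores(network)
  d <- idcScores(network, catalog)
  r <- rankByLID(network)
  n <- length(l)
  lidc <- l * (1 - r / n) + d * (r / n)
  df <- data.frame(protein = names(l), lid = unname(l),
                   idc = as.integer(unname(d)), rank = as.integer(unname(r)),
                   lidc = unname(lidc), stringsAsFactors = FALSE)
  df <- df[order(-df$lidc, df$protein), , drop = FALSE]
  rownames(df) <- NULL
  new("ScoreTable", scores = df)
}

#' Degree centrality baseline
#'
#' Plain degree per protein, the classical centrality-lethality baseline.
#'
#' @inheritParams lidScores
#' @return Named integer vector of degrees.
#' @export
degreeCentrality <- function(network) {
  stats::setNames(as.integer(igraph::degree(network)),
                  igraph::V(network)$name)
}
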