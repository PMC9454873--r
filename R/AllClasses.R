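#' @import methods
#' @importFrom stats setNames
NULL

#' ComplexCatalog: a catalog of protein complexes
#'
#' An ordered list of protein complexes, each a set of protein identifiers.
#' A protein may belong to several complexes; members are unique within a
#' complex and every complex has at least one member.
#'
#' @slot complexes Named list of character vectors; names are complex labels,
#'   elements are member identifier sets.
#' @seealso [readComplexes()], [idcScores()]
#' @export
setClass("ComplexCatalog", representation(complexes = "list"))

setValidity("ComplexCatalog", function(object) {
  cx <- object@complexes
  if (length(cx) == 0L) return(TRUE)
  if (is.null(names(cx)) || anyDuplicated(names(cx)))
    return("complexes must carry unique labels")
  for (i in seq_along(cx)) {
    m <- cx[[i]]
    if (!is.character(m) || length(m) < 1L)
      return(sprintf("complex %d must have at least one character member", i))
    if (anyDuplicated(m))
      return(sprintf("complex %d has duplicated members", i))
  }
  TRUE
})

#' Construct a ComplexCatalog
#'
#' @param complexes List of character vectors (member identifiers). Unnamed
#'   lists are labelled `C1`, `C2`, ... in order.
#' @return A [ComplexCatalog-class] object.
#' @examples
#' ComplexCatalog(list(c("A", "B", "C"), c("B", "C", "D")))
#' @export
ComplexCatalog <- function(complexes = list()) {
  complexes <- lapply(complexes, function(m) unique(as.character(m)))
  if (length(complexes) > 0L && is.null(names(complexes)))
    names(complexes) <- paste0("C", seq_along(complexes))
  new("ComplexCatalog", complexes = complexes)
}

#' GoldStandard: curated essential / non-essential protein labels
#'
#' @slot essential Character vector of essential protein identifiers.
#' @slot nonessential Character vector of non-essential identifiers (may be
#'   empty when only the essential list is known). The two sets are disjoint.
#' @export
setClass("GoldStandard",
         representation(essential = "character", nonessential = "character"))

setValidity("GoldStandard", function(object) {
  if (anyDuplicated(object@essential)) return("essential ids must be unique")
  if (anyDuplicated(object@nonessential)) return("nonessential ids must be unique")
  if (length(intersect(object@essential, object@nonessential)) > 0L)
    return("essential and nonessential sets must be disjoint")
  TRUE
})

#' Construct a GoldStandard
#'
#' @param essential Character vector of essential protein identifiers.
#' @param nonessential Optional character vector of non-essential identifiers.
#' @return A [GoldStandard-class] object.
#' @export
GoldStandard <- function(essential, nonessential = character()) {
  new("GoldStandard",
      essential = unique(as.character(essential)),
      nonessential = unique(as.character(nonessential)))
}

#' PruningReport: network statistics across the two pruning stages
#'
#' Counts of proteins and interactions before pruning, after the node-weight
#' stage, and after the edge-weight stage, together with the two thresholds
#' applied and the cut-off level.
#'
#' @slot level Character, one of `"low"`, `"medium"`, `"high"`.
#' @slot nodesInitial,edgesInitial Counts in the input network.
#' @slot nodesAfterNodeReduction,edgesAfterNodeReduction Counts after node
#'   pruning.
#' @slot nodesAfterEdgeReduction,edgesAfterEdgeReduction Counts after edge
#'   pruning (stranded degree-0 nodes dropped).
#' @slot nodeThreshold,edgeThreshold The theta_k values applied at each stage
#'   (edge threshold is `NA` when the node stage emptied the network).
#' @export
setClass("PruningReport",
         representation(level = "character",
                        nodesInitial = "integer", edgesInitial = "integer",
                        nodesAfterNodeReduction = "integer",
                        edgesAfterNodeReduction = "integer",
                        nodesAfterEdgeReduction = "integer",
                        edgesAfterEdgeReduction = "integer",
                        nodeThreshold = "numeric", edgeThreshold = "numeric"))

setValidity("PruningReport", function(object) {
  cnt <- c(object@nodesInitial, object@edgesInitial,
           object@nodesAfterNodeReduction, object@edgesAfterNodeReduction,
           object@nodesAfterEdgeReduction, object@edgesAfterEdgeReduction)
  if (any(cnt < 0L)) return("counts must be non-negative")
  if (object@nodesAfterNodeReduction > object@nodesInitial ||
      object@edgesAfterNodeReduction > object@edgesInitial ||
      object@nodesAfterEdgeReduction > object@nodesAfterNodeReduction ||
      object@edgesAfterEdgeReduction > object@edgesAfterNodeReduction)
    return("each 'after' count must not exceed the preceding count")
  if (!object@level %in% c("low", "medium", "high"))
    return("level must be low, medium or high")
  TRUE
})

#' ScoreTable: per-protein LID / IDC / RANK / LIDC scores
#'
#' Rows are ordered by the final ranking: descending LIDC, ties broken by
#' ascending protein identifier.
#'
#' @slot scores data.frame with columns `protein`, `lid`, `idc`, `rank`,
#'   `lidc`, ordered by the final ranking.
#' @export
setClass("ScoreTable", representation(scores = "data.frame"))

setValidity("ScoreTable", function(object) {
  df <- object@scores
  need <- c("protein", "lid", "idc", "rank", "lidc")
  if (!all(need %in% names(df)))
    return(paste("scores must have columns", paste(need, collapse = ", ")))
  if (nrow(df) == 0L) return("score table must be non-empty")
  if (anyDuplicated(df$protein)) return("protein ids must be unique")
  if (!setequal(df$rank, seq_len(nrow(df))))
    return("rank must be a permutation of 1..N")
  if (any(df$lid < 0) || any(df$idc < 0)) return("lid and idc must be >= 0")
  ord <- order(-df$lidc, df$protein)
  if (!identical(ord, seq_len(nrow(df))))
    return("rows must be ordered by descending lidc, ties by ascending protein")
  TRUE
})

#' EvaluationResult: confusion counts and derived metrics
#'
#' @slot tp,fp,fn,tn Confusion counts over the evaluation universe.
#' @slot precision,recall,fscore Derived metrics in [0, 1].
#' @slot universe Short description of the evaluated protein universe.
#' @export
setClass("EvaluationResult",
         representation(tp = "integer", fp = "integer",
                        fn = "integer", tn = "integer",
                        precision = "numeric", recall = "numeric",
                        fscore = "numeric", universe = "character"))

setValidity("EvaluationResult", function(object) {
  if (any(c(object@tp, object@fp, object@fn, object@tn) < 0L))
    return("confusion counts must be non-negative")
  m <- c(object@precision, object@recall, object@fscore)
  if (any(m < 0) || any(m > 1)) return("metrics must lie in [0, 1]")
  TRUE
})

#' SyntheticSpec: parameters of the planted-module benchmark generator
#'
#' @slot nBackground Number of background proteins.
#' @slot nModules Number of planted dense modules.
#' @slot moduleSize Characteristic (mean) proteins per module.
#' @slot sizeSpread Lognormal sigma of module sizes; 0 gives fixed sizes.
#' @slot pIn Within-module edge probability (must exceed `pBackground`).
#' @slot pBackground Background-background edge probability.
#' @slot pAttach Module-to-background edge probability.
#' @slot complexCoverage Probability that a planted module is emitted as a
#'   complex in the catalog.
#' @slot nNoiseComplexes Number of random background complexes added to the
#'   catalog.
#' @slot labelNoise Fraction of gold-standard labels flipped.
#' @slot seed Integer seed reproducing the full benchmark triple.
#' @export
setClass("SyntheticSpec",
         representation(nBackground = "integer", nModules = "integer",
                        moduleSize = "integer", sizeSpread = "numeric",
                        pIn = "numeric",
                        pBackground = "numeric", pAttach = "numeric",
                        complexCoverage = "numeric",
                        nNoiseComplexes = "integer",
                        labelNoise = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  p <- c(object@pIn, object@pBackground, object@pAttach,
         object@complexCoverage, object@labelNoise)
  if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0, 1]")
  if (object@pIn <= object@pBackground)
    return("pIn must exceed pBackground for a planted-structure spec")
  if (object@nBackground < 0L || object@nModules < 0L || object@moduleSize < 1L)
    return("counts must be non-negative (moduleSize >= 1)")
  if (object@sizeSpread < 0) return("sizeSpread must be >= 0")
  TRUE
})

#' SyntheticTruth: ground truth of a generated benchmark
#'
#' @slot modules Named list of character vectors: planted-module memberships.
#' @slot moduleMembers Character vector, union of all module members.
#' @slot nodes All node identifiers of the generated network.
#' @export
setClass("SyntheticTruth",
         representation(modules = "list", moduleMembers = "character",
                        nodes = "character"))

setValidity("SyntheticTruth", function(object) {
  if (!all(object@moduleMembers %in% object@nodes))
    return("module members must be nodes of the generated network")
  TRUE
})
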