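#' Accessors for lidcNet containers
#'
#' Small accessor generics: `complexes()` returns the list of member sets of a
#' [ComplexCatalog-class]; `nComplexes()` and `catalogProteins()` summarise it;
#' `essentialProteins()` / `nonessentialProteins()` read a
#' [GoldStandard-class]; `scores()` extracts the ordered data.frame of a
#' [ScoreTable-class] and `finalOrder()` its protein ordering;
#' `metrics()` extracts precision/recall/F-score of an
#' [EvaluationResult-class] and `confusionCounts()` its tp/fp/fn/tn.
#'
#' @param object An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("complexes", function(object) standardGeneric("complexes"))
#' @rdname accessors
#' @export
setGeneric("nComplexes", function(object) standardGeneric("nComplexes"))
#' @rdname accessors
#' @export
setGeneric("catalogProteins", function(object) standardGeneric("catalogProteins"))
#' @rdname accessors
#' @export
setGeneric("essentialProteins", function(object) standardGeneric("essentialProteins"))
#' @rdname accessors
#' @export
setGeneric("nonessentialProteins", function(object) standardGeneric("nonessentialProteins"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("finalOrder", function(object) standardGeneric("finalOrder"))
#' @rdname accessors
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))

#' @rdname accessors
setMethod("complexes", "ComplexCatalog", function(object) object@complexes)
#' @rdname accessors
setMethod("nComplexes", "ComplexCatalog", function(object) length(object@complexes))
#' @rdname accessors
setMethod("catalogProteins", "ComplexCatalog",
          function(object) sort(unique(unlist(object@complexes, use.names = FALSE))))
#' @rdname accessors
setMethod("essentialProteins", "GoldStandard", function(object) object@essential)
#' @rdname accessors
setMethod("nonessentialProteins", "GoldStandard", function(object) object@nonessential)
#' @rdname accessors
setMethod("scores", "ScoreTable", function(object) object@scores)
#' @rdname accessors
setMethod("finalOrder", "ScoreTable", function(object) object@scores$protein)
#' @rdname accessors
setMethod("metrics", "EvaluationResult", function(object)
  c(precision = object@precision, recall = object@recall, fscore = object@fscore))
#' @rdname accessors
setMethod("confusionCounts", "EvaluationResult", function(object)
  c(tp = object@tp, fp = object@fp, fn = object@fn, tn = object@tn))

#' Coerce a PruningReport to a named list
#'
#' @param x A [PruningReport-class].
#' @param ... Ignored.
#' @return Named list mirroring the report slots.
#' @export
as.list.PruningReport <- function(x, ...) {
  list(level = x@level,
       nodes_initial = x@nodesInitial,
       edges_initial = x@edgesInitial,
       nodes_after_node_reduction = x@nodesAfterNodeReduction,
       edges_after_node_reduction = x@edgesAfterNodeReduction,
       nodes_after_edge_reduction = x@nodesAfterEdgeReduction,
       edges_after_edge_reduction = x@edgesAfterEdgeReduction,
       node_threshold = x@nodeThreshold,
       edge_threshold = x@edgeThreshold)
}

setMethod("show", "ComplexCatalog", function(object) {
  cat(sprintf("ComplexCatalog: %d complexes, %d distinct proteins\n",
              nComplexes(object), length(catalogProteins(object))))
})

setMethod("show", "GoldStandard", function(object) {
  cat(sprintf("GoldStandard: %d essential, %d non-essential proteins\n",
              length(object@essential), length(object@nonessential)))
})

setMethod("show", "PruningReport", function(object) {
  cat(sprintf("PruningReport (%s cut-off)\n", object@level))
  cat(sprintf("  initial:              %5d proteins %6d interactions\n",
              object@nodesInitial, object@edgesInitial))
  cat(sprintf("  after node reduction: %5d proteins %6d interactions (theta = %.4f)\n",
              object@nodesAfterNodeReduction, object@edgesAfterNodeReduction,
              object@nodeThreshold))
  cat(sprintf("  after edge reduction: %5d proteins %6d interactions (theta = %.4f)\n",
              object@nodesAfterEdgeReduction, object@edgesAfterEdgeReduction,
              object@edgeThreshold))
})

setMethod("show", "ScoreTable", function(object) {
  df <- object@scores
  cat(sprintf("ScoreTable: %d proteins (descending LIDC)\n", nrow(df)))
  print(utils::head(df, 6L), row.names = FALSE)
  if (nrow(df) > 6L) cat(sprintf("  ... and %d more\n", nrow(df) - 6L))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult over %s\n", object@universe))
  cat(sprintf("  tp %d  fp %d  fn %d  tn %d\n",
              object@tp, object@fp, object@fn, object@tn))
  cat(sprintf("  precision %.4f  recall %.4f  F-score %.4f\n",
              object@precision, object@recall, object@fscore))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d background + %d x %d module nodes, ",
                     "pIn %.2f, pBackground %.3f, pAttach %.3f,\n",
                     "  complexCoverage %.2f, labelNoise %.2f, seed %d\n"),
              object@nBackground, object@nModules, object@moduleSize,
              object@pIn, object@pBackground, object@pAttach,
              object@complexCoverage, object@labelNoise, object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d modules, %d module members, %d nodes\n",
              length(object@modules), length(object@moduleMembers),
              length(object@nodes)))
})
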