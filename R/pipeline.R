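#' Run the full essential-protein prediction pipeline
#'
#' Wires the stages end to end: read inputs (or accept in-memory objects),
#' prune the network at the requested cut-off level, score the pruned network
#' with LIDC, select the predicted-essential set (top fraction and/or top-k
#' ranges), evaluate against the gold standard and trace the jackknife curve.
#' All artifacts are written under `outdir`; the run is a pure function of
#' (inputs, configuration), so repeating it reproduces the files byte for
#' byte.
#'
#' Artifacts written: `pruning_report.json`, `scores.tsv` (with a predicted
#' label column), `essential.txt` / `nonessential.txt` (top-fraction split),
#' `evaluation.json` (per-fraction and per-k metrics) and `jackknife.tsv`.
#'
#' @param edges Path to an edge-list file, or an [igraph::igraph].
#' @param complexes Path to a complex-catalog file, a [ComplexCatalog-class],
#'   or `NULL` for an empty catalog.
#' @param essential Path to a gold-standard essential list, a
#'   [GoldStandard-class], or `NULL` to skip evaluation.
#' @param outdir Output directory (created if needed).
#' @param level Cut-off level: `"low"`, `"medium"` or `"high"`.
#' @param fraction Top fraction predicted essential (default 0.2).
#' @param topK Integer vector of top-k range sizes to evaluate additionally
#'   (entries above N are dropped).
#' @param maxRank Last rank of the jackknife curve (clamped to N).
#' @param context,sd,rounding,recallDenominator Design switches passed to
#'   [nodeWeights()], [cutoffThreshold()], [selectTopFraction()] and
#'   [classificationMetrics()].
#' @param labeledComplexes Passed to [readComplexes()] when `complexes` is a
#'   path.
#' @return Invisibly, a list with `network` (pruned), `report`, `table`,
#'   `predicted`, `evaluation` (list of [EvaluationResult-class] or `NULL`),
#'   `jackknife`, and `paths` of the written artifacts.
#' @examples
#' bench <- generateBenchmark(syntheticSpec(seed = 3))
#' out <- runPipeline(bench$network, bench$catalog, bench$gold,
#'                    outdir = tempfile(), level = "high")
#' out$report
#' metrics(out$evaluation$topFraction)
#' @export
runPipeline <- function(edges, complexes = NULL, essential = NULL,
                        outdir = ".", level = c("low", "medium", "high"),
                        fraction = 0.2, topK = c(100L, 200L, 300L, 400L, 500L, 600L),
                        maxRank = 600L,
                        context = c("network", "induced"),
                        sd = c("population", "sample"),
                        rounding = c("ceil", "round", "floor"),
                        recallDenominator = c("universe", "gold"),
                        labeledComplexes = FALSE) {
  level <- levelName(if (is.character(level)) match.arg(level) else level)
  network <- if (is.character(edges)) readInteractions(edges) else edges
  catalog <- if (is.null(complexes)) ComplexCatalog()
             else if (is.character(complexes)) readComplexes(complexes, labeledComplexes)
             else complexes
  gold <- if (is.null(essential)) NULL
          else if (is.character(essential)) GoldStandard(readProteinList(essential))
          else essential

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pruned <- pruneNetwork(network, level, context = context, sd = sd)
  message(sprintf("[prune] %s cut-off: %d/%d nodes, %d/%d edges retained",
                  level,
                  pruned$report@nodesAfterEdgeReduction, pruned$report@nodesInitial,
                  pruned$report@edgesAfterEdgeReduction, pruned$report@edgesInitial))
  jsonlite::write_json(as.list(pruned$report),
                       file.path(outdir, "pruning_report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (igraph::vcount(pruned$network) == 0L)
    stop("pruning removed the whole network; nothing to score")

  table <- lidcScores(pruned$network, catalog)
  predicted <- selectTopFraction(table, fraction, rounding = rounding)
  writeScoreTable(table, file.path(outdir, "scores.tsv"), predicted = predicted)
  writeProteinList(predicted, file.path(outdir, "essential.txt"))
  writeProteinList(setdiff(finalOrder(table), predicted),
                   file.path(outdir, "nonessential.txt"))

  evaluation <- NULL
  jk <- NULL
  if (!is.null(gold)) {
    universe <- finalOrder(table)
    evaluation <- list(topFraction = classificationMetrics(
      predicted, gold, universe, recallDenominator = recallDenominator))
    ks <- topK[topK <= length(universe)]
    for (k in ks)
      evaluation[[paste0("top", k)]] <- classificationMetrics(
        selectTopK(table, k), gold, universe,
        recallDenominator = recallDenominator)
    evalOut <- lapply(evaluation, function(e)
      c(as.list(confusionCounts(e)), as.list(metrics(e))))
    evalOut$topFraction$fraction <- fraction
    evalOut$level <- level
    jsonlite::write_json(evalOut, file.path(outdir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    jk <- jackknifeCurve(table, gold,
                         min(maxRank, length(universe)))
    utils::write.table(jk, file.path(outdir, "jackknife.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(network = pruned$network, report = pruned$report,
                 table = table, predicted = predicted,
                 evaluation = evaluation, jackknife = jk,
                 paths = file.path(outdir,
                   c("pruning_report.json", "scores.tsv", "essential.txt",
                     "nonessential.txt",
                     if (!is.null(gold)) c("evaluation.json", "jackknife.tsv")))))
}
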