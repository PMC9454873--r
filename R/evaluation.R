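#' Select the top-k proteins of a ranking
#'
#' @param table A [ScoreTable-class].
#' @param k Number of proteins, 1 <= k <= N.
#' @return Character vector: the first `k` proteins of the final ordering.
#' @export
selectTopK <- function(table, k) {
  n <- nrow(scores(table))
  if (k < 1L || k > n) stop("k must be in 1..", n)
  finalOrder(table)[seq_len(k)]
}

#' Select the top fraction of a ranking
#'
#' Selects the top `ceiling(fraction * N)` proteins as predicted essential
#' (other rounding modes available); the remainder are predicted
#' non-essential.
#'
#' @param table A [ScoreTable-class].
#' @param fraction Fraction in (0, 1].
#' @param rounding How to turn `fraction * N` into a count: `"ceil"`
#'   (default), `"round"` or `"floor"`.
#' @return Character vector of predicted-essential proteins.
#' @examples
#' # a 10-protein table at fraction 0.2 selects exactly 2 proteins
#' @export
selectTopFraction <- function(table, fraction = 0.2,
                              rounding = c("ceil", "round", "floor")) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  rounding <- match.arg(rounding)
  n <- nrow(scores(table))
  k <- switch(rounding,
              ceil = ceiling(fraction * n),
              round = round(fraction * n),
              floor = floor(fraction * n))
  k <- max(1L, min(n, as.integer(k)))
  selectTopK(table, k)
}

#' Precision / recall / F-score of a predicted essential set
#'
#' Counts are taken over the evaluation universe (typically the proteins of
#' the pruned network that was scored). By default the recall denominator is
#' restricted to gold-essential proteins present in the universe
#' (`recallDenominator = "universe"`); `"gold"` instead divides by the full
#' gold-essential list. Proteins not listed as essential are treated as
#' non-essential unless `strictGold = TRUE`, in which case proteins absent
#' from both gold lists are excluded from the fp/tn bookkeeping.
#'
#' @param predicted Character vector of predicted-essential proteins
#'   (must be a subset of `universe`).
#' @param gold A [GoldStandard-class].
#' @param universe Character vector: the evaluable proteins.
#' @param recallDenominator `"universe"` (default) or `"gold"`.
#' @param strictGold Exclude proteins absent from both gold lists?
#' @return An [EvaluationResult-class].
#' @examples
#' gold <- GoldStandard(essential = paste0("P", 1:8))
#' universe <- paste0("P", 1:20)
#' predicted <- paste0("P", c(1:6, 15:18))
#' classificationMetrics(predicted, gold, universe)  # precision 0.6, recall 0.75
#' @export
classificationMetrics <- function(predicted, gold, universe,
                                  recallDenominator = c("universe", "gold"),
                                  strictGold = FALSE) {
  if (length(universe) == 0L) stop("evaluation universe is empty")
  recallDenominator <- match.arg(recallDenominator)
  predicted <- unique(predicted)
  if (!all(predicted %in% universe))
    stop("predicted proteins must lie within the evaluation universe")
  ess <- intersect(essentialProteins(gold), universe)
  neg <- if (strictGold) intersect(nonessentialProteins(gold), universe)
         else setdiff(universe, ess)
  tp <- length(intersect(predicted, ess))
  fp <- length(intersect(predicted, neg))
  tn <- length(setdiff(neg, predicted))
  fn <- if (recallDenominator == "universe") length(setdiff(ess, predicted))
        else length(essentialProteins(gold)) - tp
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  fscore <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  new("EvaluationResult", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      precision = precision, recall = recall, fscore = fscore,
      universe = sprintf("%d proteins (%d gold-essential)",
                         length(universe), length(ess)))
}

#' Jackknife curve of a ranking
#'
#' Walks the final ordering and accumulates the count of gold-essential
#' proteins among the top r ranked proteins, for r = 1..maxRank. Used to
#' compare ranking methods over the classical top-100..600 ranges.
#'
#' @param table A [ScoreTable-class].
#' @param gold A [GoldStandard-class].
#' @param maxRank Last rank of the curve; clamped to N with a warning.
#' @return data.frame with columns `rank` and `cumulativeEssential`.
#' @export
jackknifeCurve <- function(table, gold, maxRank) {
  n <- nrow(scores(table))
  if (maxRank > n) {
    warning("maxRank ", maxRank, " exceeds table size ", n, "; clamped")
    maxRank <- n
  }
  if (maxRank < 1L) stop("maxRank must be positive")
  top <- finalOrder(table)[seq_len(maxRank)]
  hits <- as.integer(top %in% essentialProteins(gold))
  data.frame(rank = seq_len(maxRank), cumulativeEssential = cumsum(hits))
}
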