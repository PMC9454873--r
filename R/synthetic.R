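#' Specify a planted-module benchmark
#'
#' The generator emulates the structure the method assumes: a sparse
#' background interactome with planted dense modules (standing in for protein
#' complexes / dense sub-modules), a complex catalog overlapping the planted
#' modules, and a gold-standard essential list enriched in module members.
#' Defaults give a ~680-protein network: 8 dense modules (pIn 0.9) of
#' characteristic size 10 planted on a 600-node sparse background
#' (pBackground 0.01). Module sizes are drawn lognormally around
#' `moduleSize` (sigma `sizeSpread`), mirroring the strong right skew of
#' curated complex catalogs; `sizeSpread = 0` fixes every module at exactly
#' `moduleSize`.
#'
#' @param nBackground Background proteins (default 600).
#' @param nModules Planted modules (default 8).
#' @param moduleSize Characteristic (mean) proteins per module (default 10).
#' @param sizeSpread Lognormal sigma of module sizes (default 0.3; 0 = fixed).
#' @param pIn Within-module edge probability (default 0.9).
#' @param pBackground Background edge probability (default 0.01).
#' @param pAttach Module-to-background edge probability (default 0.005).
#' @param complexCoverage Probability a module enters the catalog (default 0.8).
#' @param nNoiseComplexes Random background complexes added (default 0).
#' @param labelNoise Fraction of gold labels flipped (default 0).
#' @param seed Integer seed (default 1).
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nBackground = 600L, nModules = 8L, moduleSize = 10L,
                          sizeSpread = 0.3,
                          pIn = 0.9, pBackground = 0.01, pAttach = 0.005,
                          complexCoverage = 0.8, nNoiseComplexes = 0L,
                          labelNoise = 0, seed = 1L) {
  new("SyntheticSpec",
      nBackground = as.integer(nBackground), nModules = as.integer(nModules),
      moduleSize = as.integer(moduleSize), sizeSpread = sizeSpread, pIn = pIn,
      pBackground = pBackground, pAttach = pAttach,
      complexCoverage = complexCoverage,
      nNoiseComplexes = as.integer(nNoiseComplexes),
      labelNoise = labelNoise, seed = as.integer(seed))
}

# run fn with RNG set to a seed derived from the spec seed and the stage
# offset, restoring the caller's RNG state afterwards; stage offsets keep the
# three artifacts independently reproducible from one spec seed
withStageSeed <- function(spec, offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((spec@seed + offset) %% .Machine$integer.max)
  fn()
}

# all candidate unordered pairs between two index vectors (or within one)
samplePairs <- function(a, b = NULL, p) {
  if (p <= 0) return(matrix(integer(0), ncol = 2))
  if (is.null(b)) {
    if (length(a) < 2L) return(matrix(integer(0), ncol = 2))
    pairs <- t(utils::combn(a, 2L))
  } else {
    pairs <- as.matrix(expand.grid(a = a, b = b, KEEP.OUT.ATTRS = FALSE))
  }
  keep <- stats::runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

#' Generate a planted-module interaction network
#'
#' Module members are `P000001` ... (sortable, collision-free identifiers);
#' background proteins follow. Module sizes are drawn lognormally with mean
#' `moduleSize` and sigma `sizeSpread` (minimum 3; exactly `moduleSize` when
#' `sizeSpread = 0`). Each within-module pair receives an edge with
#' probability `pIn`, each background pair with `pBackground`, and each
#' module-background pair with `pAttach`. Deterministic for a fixed spec seed.
#'
#' @param spec A [SyntheticSpec-class].
#' @return List with `network` (an [igraph::igraph], possibly containing
#'   isolated background nodes) and `truth` (a [SyntheticTruth-class]).
#' @export
generatePlantedNetwork <- function(spec) {
  validObject(spec)
  res <- withStageSeed(spec, 0L, function() {
    sizes <- if (spec@nModules == 0L) integer(0)
      else if (spec@sizeSpread == 0) rep(spec@moduleSize, spec@nModules)
      else pmax(3L, as.integer(round(spec@moduleSize *
             exp(stats::rnorm(spec@nModules, -spec@sizeSpread^2 / 2,
                              spec@sizeSpread)))))
    nMod <- sum(sizes)
    nTot <- nMod + spec@nBackground
    ids <- sprintf("P%06d", seq_len(nTot))
    ends <- cumsum(sizes)
    modIdx <- lapply(seq_along(sizes), function(m)
      (c(0L, ends)[m] + 1L):ends[m])
    bgIdx <- if (spec@nBackground > 0L) (nMod + 1L):nTot else integer(0)
    within <- do.call(rbind, c(list(matrix(integer(0), ncol = 2)),
      lapply(modIdx, function(ix) samplePairs(ix, p = spec@pIn))))
    backg <- samplePairs(bgIdx, p = spec@pBackground)
    attach <- samplePairs(seq_len(nMod), bgIdx, p = spec@pAttach)
    list(edges = rbind(within, backg, attach), ids = ids, nMod = nMod,
         modules = stats::setNames(lapply(modIdx, function(ix) ids[ix]),
                                   if (length(modIdx)) paste0("M", seq_along(modIdx))))
  })
  g <- igraph::make_empty_graph(n = length(res$ids), directed = FALSE)
  igraph::V(g)$name <- res$ids
  if (nrow(res$edges) > 0L)
    g <- igraph::add_edges(g, t(res$edges))
  g <- igraph::simplify(g)
  truth <- new("SyntheticTruth", modules = res$modules,
               moduleMembers = res$ids[seq_len(res$nMod)], nodes = res$ids)
  list(network = g, truth = truth)
}

#' Generate a complex catalog overlapping the planted modules
#'
#' Each planted module is emitted as a complex with probability
#' `complexCoverage`; `nNoiseComplexes` random 5-member background complexes
#' are appended. Deterministic for a fixed spec seed.
#'
#' @param truth A [SyntheticTruth-class] from the same generation run.
#' @param spec The [SyntheticSpec-class] that produced it.
#' @return A [ComplexCatalog-class].
#' @export
generateComplexCatalog <- function(truth, spec) {
  withStageSeed(spec, 1L, function() {
    keep <- stats::runif(length(truth@modules)) < spec@complexCoverage
    cx <- truth@modules[keep]
    bg <- setdiff(truth@nodes, truth@moduleMembers)
    if (spec@nNoiseComplexes > 0L && length(bg) >= 5L) {
      noise <- lapply(seq_len(spec@nNoiseComplexes), function(i)
        sort(sample(bg, 5L)))
      names(noise) <- paste0("N", seq_along(noise))
      cx <- c(cx, noise)
    }
    out <- ComplexCatalog(cx)
    if (length(cx)) names(out@complexes) <- names(cx)
    out
  })
}

#' Generate a gold standard enriched in module members
#'
#' Module members are labelled essential and the rest non-essential; then
#' `floor(labelNoise * n)` proteins, drawn uniformly without replacement,
#' have their label flipped. Deterministic for a fixed spec seed.
#'
#' @inheritParams generateComplexCatalog
#' @return A [GoldStandard-class] covering every generated protein.
#' @export
generateGoldStandard <- function(truth, spec) {
  withStageSeed(spec, 2L, function() {
    essential <- truth@nodes %in% truth@moduleMembers
    nFlip <- floor(spec@labelNoise * length(truth@nodes))
    if (nFlip > 0L) {
      flip <- sample(length(truth@nodes), nFlip)
      essential[flip] <- !essential[flip]
    }
    GoldStandard(essential = truth@nodes[essential],
                 nonessential = truth@nodes[!essential])
  })
}

#' Generate a full benchmark triple
#'
#' Convenience wrapper producing the network, complex catalog and gold
#' standard from one spec; a single seed reproduces all three.
#'
#' @param spec A [SyntheticSpec-class].
#' @return List with `network`, `truth`, `catalog`, `gold`.
#' @examples
#' bench <- generateBenchmark(syntheticSpec(seed = 7))
#' bench$truth
#' @export
generateBenchmark <- function(spec = syntheticSpec()) {
  net <- generatePlantedNetwork(spec)
  list(network = net$network, truth = net$truth,
       catalog = generateComplexCatalog(net$truth, spec),
       gold = generateGoldStandard(net$truth, spec))
}

#' Write a benchmark triple to a directory
#'
#' Writes `edges.tsv`, `complexes.txt`, `essential.txt` and `truth.json`
#' (module membership and spec echo) under `dir`.
#'
#' @param bench A list from [generateBenchmark()].
#' @param dir Output directory (created if needed).
#' @param spec The generating [SyntheticSpec-class] (echoed into truth.json).
#' @return Invisibly, the vector of written paths.
#' @export
writeBenchmark <- function(bench, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             complexes = file.path(dir, "complexes.txt"),
             essential = file.path(dir, "essential.txt"),
             truth = file.path(dir, "truth.json"))
  writeInteractions(bench$network, paths[["edges"]])
  writeComplexes(bench$catalog, paths[["complexes"]])
  writeProteinList(essentialProteins(bench$gold), paths[["essential"]])
  truth <- list(modules = bench$truth@modules,
                moduleMembers = bench$truth@moduleMembers)
  if (!is.null(spec))
    truth$spec <- list(nBackground = spec@nBackground,
                       nModules = spec@nModules, moduleSize = spec@moduleSize,
                       sizeSpread = spec@sizeSpread,
                       pIn = spec@pIn, pBackground = spec@pBackground,
                       pAttach = spec@pAttach,
                       complexCoverage = spec@complexCoverage,
                       nNoiseComplexes = spec@nNoiseComplexes,
                       labelNoise = spec@labelNoise, seed = spec@seed)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
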