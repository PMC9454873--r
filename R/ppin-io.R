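#' Read a protein-protein interaction network from an edge list
#'
#' Reads a plain-text edge list (two whitespace/tab-separated identifier
#' columns; extra columns ignored; lines starting with `#` skipped) into a
#' simple undirected igraph. Duplicate lines and reversed duplicates collapse
#' to a single edge; self-interactions are dropped. Identifiers are
#' case-sensitive opaque strings; no aliasing is attempted, so node and edge
#' counts are reproducible.
#'
#' @param path Path to the edge-list file.
#' @param comment Comment prefix; lines starting with it are ignored.
#' @return An undirected simple [igraph::igraph] with a `parseReport`
#'   attribute: a list with `linesRead`, `duplicatesDropped`,
#'   `selfLoopsDropped`.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "A A", "A C"), f)
#' g <- readInteractions(f)
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @export
readInteractions <- function(path, comment = "#") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment) & nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0L)
    stop("empty edge-list file: ", path)
  toks <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf < 2L)) {
    bad <- which(keep)[which(nf < 2L)[1L]]
    stop(sprintf("malformed edge-list line %d in %s: need two identifiers",
                 bad, path))
  }
  u <- vapply(toks, `[[`, character(1), 1L)
  v <- vapply(toks, `[[`, character(1), 2L)
  selfloop <- u == v
  a <- pmin(u[!selfloop], v[!selfloop])
  b <- pmax(u[!selfloop], v[!selfloop])
  key <- paste0(a, "\r", b)
  dup <- duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(a[!dup], b[!dup]), directed = FALSE)
  # tokens that only ever appear in self-loop lines are still nodes
  solo <- setdiff(unique(c(u, v)), igraph::V(g)$name)
  if (length(solo) > 0L) g <- igraph::add_vertices(g, length(solo), name = solo)
  attr(g, "parseReport") <- list(linesRead = length(body),
                                 duplicatesDropped = sum(dup),
                                 selfLoopsDropped = sum(selfloop))
  g
}

#' Write an interaction network as a two-column edge list
#'
#' Edges are written with endpoints in ascending identifier order and rows
#' sorted lexicographically, so output is byte-deterministic. Isolated nodes
#' are appended as self-pair lines (`id<TAB>id`): [readInteractions()] drops
#' the self-loop but keeps the identifier as a node, so a round-trip
#' preserves them.
#'
#' @param network An undirected [igraph::igraph].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeInteractions <- function(network, path) {
  el <- igraph::as_edgelist(network)
  lines <- character(0)
  if (nrow(el) > 0L) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    lines <- sort(paste(a, b, sep = "\t"))
  }
  iso <- sort(igraph::V(network)$name[igraph::degree(network) == 0L])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, if (length(iso)) paste(iso, iso, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a protein-complex catalog
#'
#' One complex per line, members whitespace-separated. With `labeled = TRUE`
#' the first token of each line is taken as the complex label; otherwise
#' complexes are labelled `C1`, `C2`, ... in file order. Empty lines are
#' skipped with a warning.
#'
#' @param path Path to the catalog file.
#' @param labeled Does each line start with a label token?
#' @return A [ComplexCatalog-class]; file order is preserved.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B C", "B C D"), f)
#' cat <- readComplexes(f)
#' nComplexes(cat)              # 2
#' length(catalogProteins(cat)) # 4
#' @export
readComplexes <- function(path, labeled = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  empty <- !nzchar(trimws(lines))
  if (any(empty))
    warning(sum(empty), " empty line(s) skipped in ", path)
  body <- lines[!empty]
  toks <- strsplit(trimws(body), "[ \t]+")
  if (labeled) {
    labels <- vapply(toks, `[[`, character(1), 1L)
    members <- lapply(toks, `[`, -1L)
    if (any(lengths(members) == 0L))
      stop("labeled complex line with no members in ", path)
  } else {
    labels <- paste0("C", seq_along(toks))
    members <- toks
  }
  cat <- ComplexCatalog(members)
  names(cat@complexes) <- labels
  validObject(cat)
  cat
}

#' Write a protein-complex catalog
#'
#' @param catalog A [ComplexCatalog-class].
#' @param path Output path.
#' @param labeled Write the complex label as a leading token?
#' @return Invisibly, `path`.
#' @export
writeComplexes <- function(catalog, path, labeled = FALSE) {
  cx <- complexes(catalog)
  lines <- vapply(seq_along(cx), function(i) {
    m <- paste(cx[[i]], collapse = " ")
    if (labeled) paste(names(cx)[i], m) else m
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a protein identifier list
#'
#' One identifier per line; duplicates are removed (first occurrence kept).
#'
#' @param path Path to the list file.
#' @return Character vector of unique identifiers in file order.
#' @export
readProteinList <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- unique(lines[nzchar(lines)])
  if (length(ids) == 0L) stop("empty protein list: ", path)
  ids
}

#' Write a protein identifier list
#'
#' @param ids Character vector of identifiers.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProteinList <- function(ids, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(ids), con, sep = "\n")
  invisible(path)
}

#' Write a score table as TSV
#'
#' Tab-separated with header `protein  LID  IDC  RANK  LIDC  predicted`,
#' ordered by the final ranking (descending LIDC, ties by ascending protein
#' identifier), so output is byte-deterministic for a given table. The
#' `predicted` column labels proteins `essential` / `nonessential` from
#' `predicted` if supplied, otherwise from the top `fraction` of the ranking.
#'
#' @param table A [ScoreTable-class].
#' @param path Output path.
#' @param predicted Optional character vector of proteins predicted essential.
#' @param fraction Top fraction used when `predicted` is `NULL`.
#' @return Invisibly, `path`.
#' @export
writeScoreTable <- function(table, path, predicted = NULL, fraction = 0.2) {
  df <- scores(table)
  if (nrow(df) == 0L) stop("score table is empty")
  if (is.null(predicted)) predicted <- selectTopFraction(table, fraction)
  df$predicted <- ifelse(df$protein %in% predicted, "essential", "nonessential")
  names(df) <- c("protein", "LID", "IDC", "RANK", "LIDC", "predicted")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  rows <- sprintf("%s\t%.17g\t%d\t%d\t%.17g\t%s",
                  df$protein, df$LID, as.integer(df$IDC), as.integer(df$RANK),
                  df$LIDC, df$predicted)
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read a score table written by [writeScoreTable()]
#'
#' @param path Path to the TSV file.
#' @return A [ScoreTable-class]; the `predicted` column is attached as the
#'   `predicted` attribute (character vector of proteins labelled essential).
#' @export
readScoreTable <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "integer",
                                         "integer", "numeric", "character"))
  st <- new("ScoreTable",
            scores = data.frame(protein = df$protein, lid = df$LID,
                                idc = df$IDC, rank = df$RANK, lidc = df$LIDC,
                                stringsAsFactors = FALSE))
  attr(st, "predicted") <- df$protein[df$predicted == "essential"]
  st
}
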