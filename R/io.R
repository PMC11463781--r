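#' Read a CRISPR gene-effect score matrix
#'
#' Parses a DepMap-style "gene effect" CSV into the canonical genes x
#' cell-lines orientation. Gene header tokens of the form
#' \code{"SYMBOL (ENTREZ)"} are reduced to \code{SYMBOL}; empty cells become
#' \code{NA}. Scores are real-valued knockout effects where more negative
#' means stronger growth inhibition.
#'
#' @param path CSV file with one header row and one leading id column.
#' @param orientation \code{"genes-in-columns"} (the DepMap layout: cell lines
#'   in rows) or \code{"genes-in-rows"}.
#' @return numeric matrix, rownames = gene symbols, colnames = cell-line ids.
#' @export
readScoreMatrix <- function(path,
                            orientation = c("genes-in-columns",
                                            "genes-in-rows")) {
  orientation <- match.arg(orientation)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("score matrix needs an id column plus data columns")
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  tok <- trimws(as.matrix(body))
  isMissing <- tok == "" | tok == "NA" | is.na(tok)
  num <- suppressWarnings(
    matrix(as.numeric(ifelse(isMissing, NA, tok)), nrow = nrow(body),
           dimnames = list(NULL, colnames(body))))
  bad <- which(is.na(num) & !isMissing, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at data row %d, column '%s'",
                 bad[1L, 1L], colnames(body)[bad[1L, 2L]]))
  m <- matrix(num, nrow = nrow(body),
              dimnames = list(ids, colnames(body)))
  if (orientation == "genes-in-columns") m <- t(m)
  rownames(m) <- .stripEntrez(rownames(m))
  .assertUniqueIds(rownames(m), "gene")
  .assertUniqueIds(colnames(m), "cell line")
  m
}

.stripEntrez <- function(x) sub("\\s*\\([0-9]+\\)\\s*$", "", x)

.assertUniqueIds <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s ids: %s", what,
                 paste(dup, collapse = ", ")))
  invisible(ids)
}

#' Read a cell-line to context annotation table
#'
#' @param path CSV file.
#' @param cellCol,contextCol names of the cell-line and context columns.
#' @return named character vector: context keyed by cell-line id. Rows with an
#'   empty context are dropped (count logged); a cell line listed twice with
#'   the same context collapses to one entry, with conflicting contexts it is
#'   an error.
#' @export
readContextMap <- function(path, cellCol = "cell_id",
                           contextCol = "context") {
  tab <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c(cellCol, contextCol) %in% colnames(tab)))
    stop(sprintf("columns '%s' and '%s' are required", cellCol, contextCol))
  cell <- tab[[cellCol]]
  ctx <- tab[[contextCol]]
  empty <- is.na(ctx) | ctx == ""
  if (any(empty))
    .logLine("readContextMap: dropped ", sum(empty),
             " row(s) with empty context")
  cell <- cell[!empty]; ctx <- ctx[!empty]
  split_ctx <- split(ctx, cell)
  conflict <- names(split_ctx)[vapply(split_ctx,
                                      function(v) length(unique(v)) > 1L,
                                      logical(1L))]
  if (length(conflict))
    stop(sprintf("cell line(s) annotated with conflicting contexts: %s",
                 paste(conflict, collapse = ", ")))
  keep <- !duplicated(cell)
  setNames(ctx[keep], cell[keep])
}

#' Read a weighted protein-protein interaction edge list
#'
#' Loads a STRING-style TSV with two node columns and an optional confidence
#' column. Scores on a 0--1000 scale are rescaled to 0--1 (detected by a
#' maximum above 1). Edges below \code{minScore} are removed, self-loops are
#' dropped, and duplicate pairs (in either orientation) collapse keeping the
#' maximum score.
#'
#' @param path TSV file; first two columns are node ids, a numeric third
#'   column (or a column named \code{combined_score}/\code{score}/
#'   \code{weight}) is the confidence.
#' @param minScore confidence filter on the 0--1 scale; default 0.5.
#' @return data.frame with columns \code{node1, node2, weight}, one row per
#'   undirected edge (pair stored once, lexicographically ordered).
#' @export
readEdgeList <- function(path, minScore = 0.5) {
  tab <- read.delim(path, check.names = FALSE)
  if (ncol(tab) < 2L) stop("edge list needs at least two node columns")
  scoreCol <- intersect(c("combined_score", "score", "weight"),
                        colnames(tab))
  if (length(scoreCol)) {
    w <- as.numeric(tab[[scoreCol[1L]]])
  } else if (ncol(tab) >= 3L && is.numeric(tab[[3L]])) {
    w <- as.numeric(tab[[3L]])
  } else if (minScore > 0) {
    stop("no score column found but minScore > 0 requires one")
  } else {
    w <- rep(1, nrow(tab))
  }
  edges <- data.frame(node1 = as.character(tab[[1L]]),
                      node2 = as.character(tab[[2L]]),
                      weight = w, stringsAsFactors = FALSE)
  edgeList(edges, minScore = minScore)
}

#' Canonicalise an in-memory edge list
#'
#' Applies the same normalisation as \code{\link{readEdgeList}} to a
#' data.frame: rescale 0--1000 scores, drop self-loops, collapse duplicate
#' pairs keeping the max weight, filter by \code{minScore}.
#'
#' @param edges data.frame with columns \code{node1, node2, weight}.
#' @param minScore confidence filter on the 0--1 scale.
#' @return canonical edge data.frame (see \code{\link{readEdgeList}}).
#' @export
edgeList <- function(edges, minScore = 0) {
  stopifnot(all(c("node1", "node2", "weight") %in% colnames(edges)))
  w <- as.numeric(edges$weight)
  if (length(w) && max(w, na.rm = TRUE) > 1) w <- w / 1000
  a <- as.character(edges$node1); b <- as.character(edges$node2)
  keep <- a != b
  if (any(!keep)) .logLine("edgeList: dropped ", sum(!keep), " self-loop(s)")
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  wmax <- tapply(w, key, max)
  parts <- strsplit(names(wmax), "\r", fixed = TRUE)
  out <- data.frame(node1 = vapply(parts, `[`, "", 1L),
                    node2 = vapply(parts, `[`, "", 2L),
                    weight = as.numeric(wmax),
                    stringsAsFactors = FALSE)
  out <- out[out$weight >= minScore, , drop = FALSE]
  out <- out[order(out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a label assignment to CSV
#'
#' @param assignment a \linkS4class{LabelAssignment}.
#' @param path output CSV; columns \code{gene, label}, genes in lexicographic
#'   order. An empty assignment writes a header-only file.
#' @export
writeLabels <- function(assignment, path) {
  stopifnot(is(assignment, "LabelAssignment"))
  lab <- geneLabels(assignment)
  ord <- order(names(lab))
  df <- data.frame(gene = names(lab)[ord], label = unname(lab)[ord],
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read labels written by \code{writeLabels}
#' @param path CSV with columns \code{gene, label}.
#' @return named character vector of labels.
#' @export
readLabels <- function(path) {
  df <- read.csv(path, colClasses = "character")
  setNames(df$label, df$gene)
}

#' Read a plain-text gene list (one symbol per line)
#' @param path text file; blank lines ignored.
#' @return character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read a gene feature table tagged by group
#'
#' @param path CSV, first column gene id, remaining columns numeric
#'   attributes.
#' @param group feature group tag: \code{"Bio"}, \code{"CCcfs"} or
#'   \code{"N2V"}.
#' @return a \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(path, group) {
  tab <- read.csv(path, check.names = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  FeatureTable(m, group)
}

#' Construct a FeatureTable
#' @param values numeric matrix, rownames = gene ids.
#' @param group one of \code{"Bio"}, \code{"CCcfs"}, \code{"N2V"}.
#' @return a \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(values, group) {
  new("FeatureTable", values = values, group = group)
}

#' @describeIn FeatureTable the underlying matrix.
#' @param x a \code{FeatureTable}.
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureTable the group tag.
#' @export
featureGroup <- function(x) x@group

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable [%s]: %d genes x %d attributes\n",
              object@group, nrow(object@values), ncol(object@values)))
})
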