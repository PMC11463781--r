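#' Bundle scores and context annotations into a screen object
#'
#' The central container is a \link[SummarizedExperiment]{SummarizedExperiment}
#' with one assay \code{"geneEffect"} (genes x cell lines) and a
#' \code{colData} column \code{context}. Cell lines present in the matrix but
#' absent from the annotation are kept with \code{NA} context and ignored by
#' context-level operations.
#'
#' @param scores numeric genes x cell-lines matrix (e.g. from
#'   \code{\link{readScoreMatrix}}).
#' @param contexts named character vector mapping cell-line id to context
#'   (e.g. from \code{\link{readContextMap}}).
#' @return a \code{SummarizedExperiment}.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
ScoreScreen <- function(scores, contexts) {
  .assertUniqueIds(rownames(scores), "gene")
  .assertUniqueIds(colnames(scores), "cell line")
  ctx <- contexts[colnames(scores)]
  names(ctx) <- colnames(scores)
  SummarizedExperiment(
    assays = list(geneEffect = scores),
    colData = DataFrame(context = unname(ctx), row.names = colnames(scores))
  )
}

#' @describeIn ScoreScreen the gene-effect matrix of a screen.
#' @param screen a \code{SummarizedExperiment} built by \code{ScoreScreen}.
#' @export
effectScores <- function(screen) {
  SummarizedExperiment::assay(screen, "geneEffect")
}

#' @describeIn ScoreScreen the context annotation (named by cell line).
#' @export
cellContexts <- function(screen) {
  setNames(as.character(SummarizedExperiment::colData(screen)$context),
           colnames(screen))
}

#' @describeIn ScoreScreen the distinct annotated contexts.
#' @export
contextNames <- function(screen) {
  ctx <- cellContexts(screen)
  sort(unique(ctx[!is.na(ctx)]))
}

#' Filter a screen on context size and gene missingness
#'
#' Pre-filter applied before labelling: contexts with fewer than
#' \code{minCellLines} cell lines are removed together with their columns
#' (unannotated columns are removed too), then genes whose missing fraction
#' across all remaining cell lines is strictly greater than
#' \code{maxMissingFrac} are removed.
#'
#' @param screen a screen from \code{\link{ScoreScreen}}.
#' @param minCellLines minimum context size kept (default 10).
#' @param maxMissingFrac maximum tolerated per-gene missing fraction
#'   (default 0.95; a gene at exactly the limit is kept).
#' @return the filtered screen.
#' @export
filterScreen <- function(screen, minCellLines = 10, maxMissingFrac = 0.95) {
  ctx <- cellContexts(screen)
  sizes <- table(ctx[!is.na(ctx)])
  keepCtx <- names(sizes)[sizes >= minCellLines]
  dropCtx <- setdiff(names(sizes), keepCtx)
  if (length(dropCtx))
    .logLine("filterScreen: removed context(s) with < ", minCellLines,
             " cell lines: ", paste(dropCtx, collapse = ", "))
  keepCells <- !is.na(ctx) & ctx %in% keepCtx
  if (!any(keepCells)) stop("no context survives the cell-line filter")
  out <- screen[, keepCells]
  m <- effectScores(out)
  missFrac <- rowMeans(is.na(m))
  keepGenes <- missFrac <= maxMissingFrac
  if (any(!keepGenes))
    .logLine("filterScreen: removed ", sum(!keepGenes),
             " gene(s) with missing fraction > ", maxMissingFrac)
  if (!any(keepGenes)) stop("no gene survives the missingness filter")
  out[keepGenes, ]
}
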