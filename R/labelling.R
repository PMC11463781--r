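#' Otsu threshold of a score distribution
#'
#' Builds a 256-bin histogram spanning \code{[min, max]} of the finite values
#' and returns the cut maximising the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2}. The returned threshold is the upper edge
#' of the selected bin mapped back to score units, so scores strictly below
#' it fall in the low (essential) class.
#'
#' @param values numeric vector; \code{NA} are dropped. At least two distinct
#'   finite values are required.
#' @param nbins histogram resolution (default 256).
#' @return scalar threshold in score units, strictly between \code{min} and
#'   \code{max} of the values used.
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least two finite values")
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("degenerate input: all values identical")
  width <- (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / width), nbins - 1L)  # values at hi -> last bin
  counts <- tabulate(idx + 1L, nbins = nbins)
  sums <- vapply(split(v, factor(idx, levels = 0:(nbins - 1L))), sum, 0)
  sums[is.na(sums)] <- 0
  w0 <- cumsum(counts)
  s0 <- cumsum(sums)                # exact value mass below each bin edge
  total <- w0[nbins]; sumAll <- s0[nbins]
  # candidate cut after bin k (k = 1 .. nbins-1)
  k <- seq_len(nbins - 1L)
  n0 <- w0[k]; n1 <- total - n0
  valid <- n0 > 0 & n1 > 0
  mu0 <- s0[k] / n0
  mu1 <- (sumAll - s0[k]) / n1
  bcv <- ifelse(valid, (n0 / total) * (n1 / total) * (mu0 - mu1)^2, -Inf)
  best <- which.max(bcv)
  lo + best * width
}

#' Binarise one cell line's scores at its Otsu threshold
#'
#' @param column named numeric vector of one cell line's scores across genes.
#' @param cellId identifier used in the threshold record.
#' @return list with \code{labels} (named character, \code{"E"} if score <
#'   threshold, \code{"NE"} if >= , \code{NA} where the score is missing) and
#'   \code{threshold} (data.frame \code{cell_id, threshold, n_used}). A
#'   constant column yields all-\code{NE} labels with a warning logged: a flat
#'   score profile carries no evidence of essentiality.
#' @export
binariseCellLine <- function(column, cellId = "cell") {
  ok <- is.finite(column)
  lab <- rep(NA_character_, length(column))
  names(lab) <- names(column)
  if (sum(ok) < 1L) stop("column has no usable scores")
  if (length(unique(column[ok])) < 2L) {
    .logLine("binariseCellLine: constant column '", cellId,
             "', labelling all genes NE")
    lab[ok] <- "NE"
    thr <- NA_real_
  } else {
    thr <- otsuThreshold(column[ok])
    lab[ok] <- ifelse(column[ok] < thr, "E", "NE")
  }
  list(labels = lab,
       threshold = data.frame(cell_id = cellId, threshold = thr,
                              n_used = sum(ok), stringsAsFactors = FALSE))
}

# Aggregate a genes x units partial-label matrix by row-wise mode with an
# explicit tie-break; genes with no usable partial label are dropped.
.aggregateMode <- function(partials, classes, tieBreak, context,
                           thresholds = data.frame()) {
  nOK <- rowSums(!is.na(partials))
  dropped <- rownames(partials)[nOK == 0L]
  if (length(dropped))
    .logLine("labelling: omitted ", length(dropped),
             " gene(s) with no usable score in context '", context, "'")
  keep <- nOK > 0L
  part <- partials[keep, , drop = FALSE]
  labels <- apply(part, 1L, function(r) .modeLabel(r[!is.na(r)], tieBreak))
  new("LabelAssignment", labels = labels, partials = part,
      classes = classes, context = context, thresholds = thresholds,
      dropped = dropped)
}

#' Label genes within one context
#'
#' The context-specific labelling pass: select the context's cell lines,
#' binarise each at its own Otsu threshold, then assign each gene the mode of
#' its per-cell-line labels, ties resolved to \code{NE}.
#'
#' @param screen a (filtered) screen from \code{\link{ScoreScreen}}.
#' @param context context id to label.
#' @return a \linkS4class{LabelAssignment} with per-cell-line partial labels
#'   and the per-cell-line thresholds as a sidecar data.frame.
#' @export
labelContext <- function(screen, context) {
  ctx <- cellContexts(screen)
  cells <- names(ctx)[!is.na(ctx) & ctx == context]
  if (!length(cells)) stop(sprintf("unknown context '%s'", context))
  m <- effectScores(screen)[, cells, drop = FALSE]
  parts <- matrix(NA_character_, nrow(m), ncol(m),
                  dimnames = dimnames(m))
  thr <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    b <- binariseCellLine(m[, j], colnames(m)[j])
    parts[, j] <- b$labels
    thr[[j]] <- b$threshold
  }
  .aggregateMode(parts, classes = c("E", "NE"), tieBreak = "NE",
                 context = context, thresholds = do.call(rbind, thr))
}

#' Label common essential genes across all contexts
#'
#' Runs \code{\link{labelContext}} for every context and aggregates the
#' context-level labels by a second mode (ties to \code{NE}). The two-level
#' mode gives each context one vote regardless of how many cell lines it
#' contributed, avoiding the bias of unequal context sizes.
#'
#' @param screen a (filtered) screen.
#' @param contextAssignments optional pre-computed list of per-context
#'   \linkS4class{LabelAssignment}s (keyed by context) to reuse.
#' @return a \linkS4class{LabelAssignment} whose partial labels are the
#'   per-context final labels (units = contexts, \code{context = "common"}).
#' @export
labelCommon <- function(screen, contextAssignments = NULL) {
  ctxs <- contextNames(screen)
  if (!length(ctxs)) stop("screen has no annotated contexts")
  if (is.null(contextAssignments))
    contextAssignments <- lapply(setNames(ctxs, ctxs),
                                 function(cc) labelContext(screen, cc))
  genes <- sort(unique(unlist(lapply(contextAssignments,
                                     function(a) names(geneLabels(a))))))
  parts <- matrix(NA_character_, length(genes), length(ctxs),
                  dimnames = list(genes, ctxs))
  for (cc in ctxs) {
    lab <- geneLabels(contextAssignments[[cc]])
    parts[names(lab), cc] <- unname(lab)
  }
  .aggregateMode(parts, classes = c("E", "NE"), tieBreak = "NE",
                 context = "common")
}

#' Uncommon context-specific essential genes
#'
#' The genes essential in a context but not commonly essential:
#' \code{E(context) \\ E(common)}.
#'
#' @param cs context-level \linkS4class{LabelAssignment}.
#' @param common across-context \linkS4class{LabelAssignment} from
#'   \code{\link{labelCommon}}.
#' @return character vector of gene ids, sorted.
#' @export
ucsGenes <- function(cs, common) {
  csE <- essentialGenes(cs)
  cE <- essentialGenes(common)
  sort(setdiff(csE, cE))
}

#' Three-class refinement: E / aE / sNE
#'
#' Keeps the two-class essential set untouched and splits the not-essential
#' genes of a context into almost-essential (aE) and strongly-not-essential
#' (sNE): each cell-line column is restricted to the genes whose final
#' two-class label is NE, a second Otsu pass thresholds that restricted
#' distribution, and per-gene labels are again the mode over cell lines,
#' ties resolved to \code{sNE}.
#'
#' @param screen a (filtered) screen.
#' @param context context id.
#' @param twoClass optional pre-computed two-class assignment for the context.
#' @return a \linkS4class{LabelAssignment} with classes
#'   \code{c("E","aE","sNE")} partitioning the context's labelled genes.
#' @export
labelThreeClass <- function(screen, context, twoClass = NULL) {
  if (is.null(twoClass)) twoClass <- labelContext(screen, context)
  lab2 <- geneLabels(twoClass)
  eGenes <- names(lab2)[lab2 == "E"]
  neGenes <- names(lab2)[lab2 == "NE"]
  ctx <- cellContexts(screen)
  cells <- names(ctx)[!is.na(ctx) & ctx == context]
  m <- effectScores(screen)[neGenes, cells, drop = FALSE]
  parts <- matrix(NA_character_, nrow(m), ncol(m), dimnames = dimnames(m))
  thr <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    b <- binariseCellLine(m[, j], colnames(m)[j])
    parts[, j] <- c(E = "aE", NE = "sNE")[b$labels]
    thr[[j]] <- b$threshold
  }
  sub <- .aggregateMode(parts, classes = c("aE", "sNE"), tieBreak = "sNE",
                        context = context, thresholds = do.call(rbind, thr))
  # assemble E + refined NE; E partials carried over from the two-class run
  labels <- c(setNames(rep("E", length(eGenes)), eGenes), geneLabels(sub))
  allParts <- matrix(NA_character_, length(labels), length(cells),
                     dimnames = list(names(labels), cells))
  p2 <- partialLabels(twoClass)
  eKeep <- intersect(eGenes, rownames(p2))
  allParts[eKeep, colnames(p2)] <- p2[eKeep, , drop = FALSE]
  allParts[rownames(sub@partials), colnames(sub@partials)] <- sub@partials
  new("LabelAssignment", labels = labels, partials = allParts,
      classes = c("E", "aE", "sNE"), context = context,
      thresholds = do.call(rbind, thr),
      dropped = union(twoClass@dropped, sub@dropped))
}

#' @describeIn LabelAssignment-class final per-gene labels (named character).
#' @param x a \code{LabelAssignment}.
#' @export
geneLabels <- function(x) x@labels

#' @describeIn LabelAssignment-class the per-unit partial label matrix.
#' @export
partialLabels <- function(x) x@partials

#' @describeIn LabelAssignment-class per-cell-line Otsu thresholds
#'   (data.frame \code{cell_id, threshold, n_used}).
#' @export
cellThresholds <- function(x) x@thresholds

#' @describeIn LabelAssignment-class gene ids with a given label
#'   (default the essential class).
#' @param label which label to extract.
#' @export
essentialGenes <- function(x, label = "E") {
  sort(names(x@labels)[x@labels == label])
}

#' LabelAssignment accessors
#' @name LabelAssignment-class
#' @aliases LabelAssignment
NULL

setMethod("show", "LabelAssignment", function(object) {
  tab <- table(factor(object@labels, levels = object@classes))
  cat(sprintf("LabelAssignment for context '%s': %d genes (%s)\n",
              object@context, length(object@labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (length(object@dropped))
    cat(sprintf("  %d gene(s) omitted (no usable score)\n",
                length(object@dropped)))
})
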