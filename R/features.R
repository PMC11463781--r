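#' Assemble the model matrix from feature tables and labels
#'
#' Inner-joins the selected feature groups and the labels on gene id. Genes
#' that carry a label but no feature row cannot be predicted; they are
#' excluded and recorded (see \code{\link{unpredictedGenes}}). Genes with
#' partial missingness are kept; imputation happens later, with statistics
#' from the fitting set only (\code{\link{imputeMissing}}).
#'
#' @param tables list of \linkS4class{FeatureTable}s.
#' @param labels a \linkS4class{LabelAssignment} or a named character vector
#'   of labels.
#' @param groups which feature groups to use (subset of
#'   \code{c("Bio","CCcfs","N2V")}).
#' @param positive,negative label values mapped to 1 and 0; genes with other
#'   labels are excluded (this is how the three-class pairwise problems,
#'   e.g. E vs sNE, are set up).
#' @return a \linkS4class{ModelMatrix}.
#' @export
assembleModelMatrix <- function(tables, labels,
                                groups = c("Bio", "CCcfs", "N2V"),
                                positive = "E", negative = "NE") {
  if (is(labels, "LabelAssignment")) labels <- geneLabels(labels)
  groups <- match.arg(groups, several.ok = TRUE)
  tables <- Filter(function(t) featureGroup(t) %in% groups, tables)
  if (!length(tables)) stop("no feature table in the selected groups")
  labels <- labels[labels %in% c(positive, negative)]
  genes <- names(labels)
  for (t in tables) genes <- intersect(genes, rownames(featureValues(t)))
  # drop genes whose joined feature row is entirely missing
  if (length(genes)) {
    allNA <- Reduce(`&`, lapply(tables, function(t)
      rowSums(!is.na(featureValues(t)[genes, , drop = FALSE])) == 0L))
    genes <- genes[!allNA]
  }
  if (!length(genes)) stop("empty join between features and labels")
  genes <- sort(genes)
  unpred <- sort(setdiff(names(labels), genes))
  if (length(unpred))
    .logLine("assembleModelMatrix: ", length(unpred),
             " labelled gene(s) not predicted as no attributes were",
             " retrieved")
  mats <- lapply(tables, function(t) featureValues(t)[genes, , drop = FALSE])
  x <- do.call(cbind, mats)
  grp <- unlist(lapply(tables, function(t)
    rep(featureGroup(t), ncol(featureValues(t)))))
  y <- setNames(as.integer(labels[genes] == positive), genes)
  new("ModelMatrix", x = x, groups = unname(grp), y = y,
      positiveClass = positive, negativeClass = negative,
      unpredicted = unpred)
}

#' @describeIn assembleModelMatrix feature matrix of a ModelMatrix.
#' @param mm a \code{ModelMatrix}.
#' @export
modelFeatures <- function(mm) mm@x

#' @describeIn assembleModelMatrix 0/1 label vector.
#' @export
modelLabels <- function(mm) mm@y

#' @describeIn assembleModelMatrix per-column group tags.
#' @export
featureGroups <- function(mm) mm@groups

#' @describeIn assembleModelMatrix labelled genes excluded for lack of
#'   features.
#' @export
unpredictedGenes <- function(mm) mm@unpredicted

setMethod("show", "ModelMatrix", function(object) {
  cat(sprintf(
    "ModelMatrix: %d genes x %d attributes (%s); %d positive (%s)\n",
    nrow(object@x), ncol(object@x),
    paste(sprintf("%s=%d", names(table(object@groups)),
                  table(object@groups)), collapse = ", "),
    sum(object@y), object@positiveClass))
})

.mmReplaceX <- function(mm, x, groups = mm@groups) {
  new("ModelMatrix", x = x, groups = groups, y = mm@y,
      positiveClass = mm@positiveClass, negativeClass = mm@negativeClass,
      unpredicted = mm@unpredicted)
}

#' Impute missing feature values with fitting-set medians
#'
#' @param mm a \linkS4class{ModelMatrix}.
#' @param fitRows gene ids defining the fitting set on which medians are
#'   computed (default: all rows). Medians are applied to every row, so
#'   held-out rows never contribute statistics.
#' @return the ModelMatrix with \code{NA}s replaced.
#' @export
imputeMissing <- function(mm, fitRows = rownames(mm@x)) {
  x <- mm@x
  med <- apply(x[fitRows, , drop = FALSE], 2L, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in which(colSums(is.na(x)) > 0L))
    x[is.na(x[, j]), j] <- med[j]
  .mmReplaceX(mm, x)
}

#' Remove attributes constant on the fitting set
#'
#' A column with at most one distinct non-missing value on \code{fitRows}
#' carries no information and would break z-scoring; such columns are
#' removed and their names logged.
#'
#' @inheritParams imputeMissing
#' @return the ModelMatrix without constant columns.
#' @export
dropConstant <- function(mm, fitRows = rownames(mm@x)) {
  xf <- mm@x[fitRows, , drop = FALSE]
  nDistinct <- apply(xf, 2L, function(col) length(unique(col[!is.na(col)])))
  keep <- nDistinct > 1L
  if (!any(keep)) stop("all attributes are constant on the fitting set")
  if (any(!keep))
    .logLine("dropConstant: removed ", sum(!keep), " attribute(s): ",
             paste(colnames(mm@x)[!keep], collapse = ", "))
  .mmReplaceX(mm, mm@x[, keep, drop = FALSE], mm@groups[keep])
}

#' Z-score Bio and CCcfs attributes on fitting-set statistics
#'
#' Per column in groups \code{Bio} and \code{CCcfs}: subtract the mean and
#' divide by the standard deviation computed on \code{fitRows} only. The
#' \code{N2V} embedding columns are returned untouched. Applying the
#' fit-row statistics to held-out rows keeps the transform leak-free.
#'
#' @inheritParams imputeMissing
#' @return the standardised ModelMatrix.
#' @export
standardise <- function(mm, fitRows = rownames(mm@x)) {
  x <- mm@x
  cols <- which(mm@groups %in% c("Bio", "CCcfs"))
  if (length(cols)) {
    xf <- x[fitRows, cols, drop = FALSE]
    mu <- colMeans(xf, na.rm = TRUE)
    sg <- apply(xf, 2L, sd, na.rm = TRUE)
    sg[!is.finite(sg) | sg == 0] <- 1
    x[, cols] <- sweep(sweep(x[, cols, drop = FALSE], 2L, mu), 2L, sg, "/")
  }
  .mmReplaceX(mm, x)
}

# Fold-wise preprocessing used by the CV harness: impute -> drop constant ->
# standardise, all statistics from fitRows.
.preprocess <- function(mm, fitRows) {
  mm <- imputeMissing(mm, fitRows)
  mm <- suppressMessages(dropConstant(mm, fitRows))
  standardise(mm, fitRows)
}

#' Subset a ModelMatrix by gene
#' @param mm a \linkS4class{ModelMatrix}.
#' @param genes gene ids to keep.
#' @return the row-subset ModelMatrix.
#' @export
subsetGenes <- function(mm, genes) {
  new("ModelMatrix", x = mm@x[genes, , drop = FALSE], groups = mm@groups,
      y = mm@y[genes], positiveClass = mm@positiveClass,
      negativeClass = mm@negativeClass, unpredicted = mm@unpredicted)
}
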