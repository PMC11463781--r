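#' @import methods
#' @importFrom stats median sd var quantile rnorm runif setNames
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

#' Per-gene essentiality label assignment
#'
#' Holds the outcome of one labelling pass: the final per-gene label, the
#' per-unit partial labels it was aggregated from (units are cell lines for a
#' context-level run, contexts for the common-gene run), and the thresholds
#' used to binarise each unit.
#'
#' @slot labels named character vector, one final label per gene, values drawn
#'   from \code{classes}.
#' @slot partials character matrix (genes x units) of partial labels; \code{NA}
#'   where a score was missing.
#' @slot classes character vector of admissible labels, e.g. \code{c("E","NE")}
#'   or \code{c("E","aE","sNE")}.
#' @slot context identifier of the context this assignment describes
#'   (\code{"common"} for the across-context aggregation).
#' @slot thresholds data.frame with columns \code{cell_id}, \code{threshold},
#'   \code{n_used}; empty for aggregated assignments.
#' @slot dropped character vector of genes omitted because they had no usable
#'   score in the context.
#' @exportClass LabelAssignment
setClass("LabelAssignment",
  representation(
    labels     = "character",
    partials   = "matrix",
    classes    = "character",
    context    = "character",
    thresholds = "data.frame",
    dropped    = "character"
  )
)

setValidity("LabelAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    msg <- c(msg, "labels must be uniquely named by gene")
  if (!all(object@labels %in% object@classes))
    msg <- c(msg, "labels outside the declared class set")
  if (nrow(object@partials) > 0L &&
      !identical(rownames(object@partials), names(object@labels)))
    msg <- c(msg, "partial-label rows must match labelled genes")
  if (nrow(object@partials) > 0L) {
    n_ok <- rowSums(!is.na(object@partials))
    if (any(n_ok == 0L))
      msg <- c(msg, "every labelled gene needs at least one partial label")
  }
  if (length(msg)) msg else TRUE
})

#' Gene feature table tagged by group
#'
#' A genes x attributes real-valued table whose columns all belong to one
#' feature group (\code{Bio}, \code{CCcfs} or \code{N2V}). Missing values are
#' permitted; they are imputed later, on the fitting set only.
#'
#' @slot values numeric matrix, rownames = gene ids, colnames = attributes.
#' @slot group scalar character, one of \code{"Bio"}, \code{"CCcfs"},
#'   \code{"N2V"}.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", group = "character"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (length(object@group) != 1L || !object@group %in% c("Bio", "CCcfs", "N2V"))
    msg <- c(msg, "group must be one of Bio, CCcfs, N2V")
  if (is.null(rownames(object@values)) || anyDuplicated(rownames(object@values)))
    msg <- c(msg, "rows must be uniquely named by gene")
  if (is.null(colnames(object@values)) || anyDuplicated(colnames(object@values)))
    msg <- c(msg, "columns must be uniquely named")
  if (length(msg)) msg else TRUE
})

#' Model matrix: features joined to binary labels
#'
#' @slot x numeric matrix, genes x attributes (may contain \code{NA} until the
#'   fitting-set imputation is applied).
#' @slot groups character vector, one group tag per column of \code{x}.
#' @slot y named integer vector of labels aligned to \code{rownames(x)};
#'   1 = minority/positive class (essential), 0 = majority class.
#' @slot positiveClass,negativeClass the label names behind 1 and 0.
#' @slot unpredicted genes that carried a label but no feature row (excluded
#'   from the matrix, reported for audit).
#' @exportClass ModelMatrix
setClass("ModelMatrix",
  representation(
    x = "matrix", groups = "character", y = "integer",
    positiveClass = "character", negativeClass = "character",
    unpredicted = "character"
  )
)

setValidity("ModelMatrix", function(object) {
  msg <- character()
  if (length(object@groups) != ncol(object@x))
    msg <- c(msg, "one group tag per column required")
  if (!identical(names(object@y), rownames(object@x)))
    msg <- c(msg, "labels must align with matrix rows")
  if (!all(object@y %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Trained splitting voting ensemble
#'
#' @slot members list of fitted base-learner models, one per majority-class
#'   slice.
#' @slot sliceAssignment named integer vector mapping each majority-class
#'   training row id to the member it was assigned to.
#' @slot n number of members.
#' @slot learner the base-learner contract used (see \code{\link{xgbLearner}}).
#' @slot featureNames training column schema; prediction enforces it.
#' @slot classes character(2): minority (positive) then majority label.
#' @exportClass SVEModel
setClass("SVEModel",
  representation(
    members = "list", sliceAssignment = "integer", n = "integer",
    learner = "list", featureNames = "character", classes = "character"
  )
)

setValidity("SVEModel", function(object) {
  msg <- character()
  if (length(object@members) != object@n)
    msg <- c(msg, "member count must equal n")
  if (length(object@sliceAssignment) &&
      !all(object@sliceAssignment %in% seq_len(object@n)))
    msg <- c(msg, "slice assignment outside 1..n")
  sz <- tabulate(object@sliceAssignment, nbins = object@n)
  if (object@n > 1L && (max(sz) - min(sz)) > 1L)
    msg <- c(msg, "slice sizes must differ by at most 1")
  if (length(msg)) msg else TRUE
})

#' Cross-validation report
#'
#' @slot confusion data.frame with one row per round: \code{round, tp, fp, tn,
#'   fn} pooled over that round's folds.
#' @slot metricsByRound data.frame, one row per round, columns \code{BA,
#'   Sensitivity, Specificity, MCC, AUC}.
#' @slot probs numeric matrix genes x rounds of held-out predicted
#'   probabilities.
#' @slot truth named integer vector of true 0/1 labels.
#' @slot folds list (length rounds) of named integer fold indices.
#' @slot k,rounds,threshold CV geometry and the hard-label cut-off.
#' @exportClass CVReport
setClass("CVReport",
  representation(
    confusion = "data.frame", metricsByRound = "data.frame",
    probs = "matrix", truth = "integer", folds = "list",
    k = "integer", rounds = "integer", threshold = "numeric"
  )
)

setValidity("CVReport", function(object) {
  msg <- character()
  if (ncol(object@probs) != object@rounds)
    msg <- c(msg, "one probability column per round required")
  if (!identical(rownames(object@probs), names(object@truth)))
    msg <- c(msg, "probability rows must align with truth")
  if (length(msg)) msg else TRUE
})
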