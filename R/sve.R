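#' Number of ensemble members for a splitting voting ensemble
#'
#' The member count is chosen from the class distribution so that each base
#' learner sees a roughly balanced training set: one slice of the majority
#' class of about minority size, plus all minority samples.
#'
#' @param nMajority,nMinority training counts of the two classes.
#' @return \code{max(1, floor(nMajority / nMinority))}.
#' @export
chooseSliceCount <- function(nMajority, nMinority) {
  if (nMinority < 1L) stop("degenerate training set: no minority samples")
  max(1L, as.integer(nMajority %/% nMinority))
}

#' Gradient-boosted tree base learner
#'
#' The default base learner of the ensemble: an xgboost binary classifier
#' run single-threaded for determinism. Any list with the same
#' \code{fit(x, y)} / \code{predict(model, x)} contract can replace it
#' (see \code{\link{rangerLearner}}).
#'
#' @param nrounds,maxDepth,eta boosting rounds, tree depth, learning rate.
#' @param ... further xgboost parameters.
#' @return a base-learner contract list with elements \code{name},
#'   \code{fit} and \code{predict}.
#' @export
xgbLearner <- function(nrounds = 100L, maxDepth = 4L, eta = 0.3, ...) {
  extra <- list(...)
  list(
    name = "xgboost",
    fit = function(x, y) {
      params <- c(list(objective = "binary:logistic", max_depth = maxDepth,
                       eta = eta, nthread = 1L), extra)
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = nrounds, verbose = 0L)
    },
    predict = function(model, x) {
      as.numeric(predict(model, xgboost::xgb.DMatrix(x, nthread = 1L)))
    }
  )
}

#' Random-forest base learner (alternative ensemble member)
#'
#' @param numTrees forest size.
#' @return a base-learner contract list (requires the \pkg{ranger} package).
#' @export
rangerLearner <- function(numTrees = 200L) {
  list(
    name = "ranger",
    fit = function(x, y) {
      df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x,
                       check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = numTrees, probability = TRUE,
                     num.threads = 1L,
                     seed = sample.int(.Machine$integer.max, 1L))
    },
    predict = function(model, x) {
      as.numeric(predict(model, data.frame(x, check.names = FALSE),
                         num.threads = 1L)$predictions[, "1"])
    }
  )
}

#' Fit a splitting voting ensemble
#'
#' Majority-class rows are shuffled with \code{seed} and dealt round-robin
#' into \code{n} near-equal slices (\code{n} from
#' \code{\link{chooseSliceCount}} unless overridden). Member \code{i} is
#' trained on slice \code{i} together with all minority rows. Prediction
#' soft-votes by averaging the members' class-1 probabilities.
#'
#' @param x numeric feature matrix with rownames.
#' @param y named integer 0/1 labels aligned to \code{rownames(x)}; the
#'   minority class is detected from the counts (1 wins a tie).
#' @param learner base-learner contract (default \code{\link{xgbLearner}()}).
#' @param seed seed for the slice shuffle (and any learner-internal draw).
#' @param nOverride force the member count.
#' @return an \linkS4class{SVEModel}.
#' @export
sveFit <- function(x, y, learner = xgbLearner(), seed = 1L,
                   nOverride = NULL) {
  stopifnot(identical(rownames(x), names(y)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  counts <- table(factor(y, levels = c(0L, 1L)))
  minLab <- if (counts["1"] <= counts["0"]) 1L else 0L
  majLab <- 1L - minLab
  majRows <- names(y)[y == majLab]
  minRows <- names(y)[y == minLab]
  n <- if (is.null(nOverride)) {
    chooseSliceCount(length(majRows), length(minRows))
  } else {
    stopifnot(nOverride >= 1L)
    as.integer(nOverride)
  }
  shuffled <- .withSeed(seed, sample(majRows))
  assignment <- setNames(rep_len(seq_len(n), length(shuffled)), shuffled)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- c(names(assignment)[assignment == i], minRows)
    fit <- try(.withSeed(.deriveSeed(seed, i),
                         learner$fit(x[rows, , drop = FALSE],
                                     as.numeric(y[rows] == minLab))),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      stop(sprintf("base learner failed on ensemble member %d: %s",
                   i, attr(fit, "condition")$message))
    members[[i]] <- fit
  }
  classes <- c(as.character(minLab), as.character(majLab))
  new("SVEModel", members = members, sliceAssignment = assignment,
      n = n, learner = learner, featureNames = colnames(x),
      classes = classes)
}

#' Soft-vote probability of the minority (positive) class
#'
#' @param model an \linkS4class{SVEModel}.
#' @param x feature rows with the training column schema.
#' @return arithmetic mean of the member probabilities, one value per row.
#' @export
svePredictProba <- function(model, x) {
  if (!identical(colnames(x), model@featureNames))
    stop("feature schema mismatch with the trained model")
  probs <- vapply(model@members,
                  function(m) model@learner$predict(m, x),
                  numeric(nrow(x)))
  if (nrow(x) == 1L) probs <- matrix(probs, nrow = 1L)
  setNames(rowMeans(probs), rownames(x))
}

#' Hard labels from the ensemble probability
#'
#' @inheritParams svePredictProba
#' @param threshold decision cut-off; a probability exactly at the threshold
#'   is called positive.
#' @return named integer vector: 1 where probability >= threshold.
#' @export
svePredict <- function(model, x, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  p <- svePredictProba(model, x)
  setNames(as.integer(p >= threshold), names(p))
}

#' @describeIn sveFit the majority-row slice assignment of a fitted model.
#' @param model an \code{SVEModel}.
#' @export
sliceAssignment <- function(model) model@sliceAssignment

setMethod("show", "SVEModel", function(object) {
  cat(sprintf(
    "SVEModel: %d member(s) [%s], %d majority rows sliced, positive class '%s'\n",
    object@n, object@learner$name, length(object@sliceAssignment),
    object@classes[1L]))
})
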