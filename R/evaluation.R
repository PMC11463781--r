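#' Stratified fold assignment
#'
#' Shuffles each class with the seed and deals rows to folds through one
#' continuing round-robin cursor, so fold sizes differ by at most one
#' overall and per class.
#'
#' @param y named integer 0/1 labels.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return named integer vector of fold indices in \code{1..k}.
#' @export
stratifiedFolds <- function(y, k = 5L, seed = 1L) {
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts < k))
    stop(sprintf("each class needs at least k = %d members", k))
  folds <- integer(length(y))
  names(folds) <- names(y)
  cursor <- 0L
  .withSeed(seed, {
    for (cls in c(1L, 0L)) {
      rows <- sample(names(y)[y == cls])
      folds[rows] <- ((cursor + seq_along(rows) - 1L) %% k) + 1L
      cursor <- (cursor + length(rows)) %% k
    }
  })
  folds
}

#' Classification metric panel
#'
#' Computes Sensitivity \code{tp/(tp+fn)}, Specificity \code{tn/(tn+fp)},
#' their mean (Balanced Accuracy), the Matthews correlation coefficient and
#' rank-based ROC-AUC (ties handled by midranks). An MCC with a zero
#' denominator is reported as \code{NA}.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @param probs,truth optional probability / 0-1 truth vectors for AUC.
#' @return named numeric vector \code{Sensitivity, Specificity, BA, MCC}
#'   (+ \code{AUC} when probabilities are given).
#' @export
metricsPanel <- function(tp, fp, tn, fn, probs = NULL, truth = NULL) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ba <- (sens + spec) / 2
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) NA_real_ else (tp * tn - fp * fn) / denom
  out <- c(Sensitivity = sens, Specificity = spec, BA = ba, MCC = mcc)
  if (!is.null(probs)) out <- c(out, AUC = rocAUC(probs, truth))
  out
}

#' Rank-statistic ROC-AUC
#'
#' @param probs predicted probabilities.
#' @param truth 0/1 labels.
#' @return the probability that a random positive outranks a random
#'   negative, ties counted half (midranks).
#' @export
rocAUC <- function(probs, truth) {
  truth <- as.integer(truth)
  nPos <- sum(truth == 1L)
  nNeg <- sum(truth == 0L)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(probs, ties.method = "average")
  (sum(r[truth == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Repeated stratified cross-validation of the splitting voting ensemble
#'
#' For each round a fresh stratified k-fold split is drawn (round seed =
#' run seed + round index); per fold, preprocessing (median imputation,
#' constant removal, z-scoring of Bio/CCcfs) is fitted on the training
#' folds only, the ensemble is fitted, and the held-out fold predicted.
#' Every gene is predicted exactly once per round. Metrics are computed on
#' the pooled per-round confusion and averaged over rounds.
#'
#' @param mm a \linkS4class{ModelMatrix}.
#' @param learner base-learner contract (default \code{\link{xgbLearner}()}).
#' @param k folds per round (default 5).
#' @param rounds repetitions with different partitions (default 10).
#' @param seed run seed.
#' @param threshold hard-label cut-off for the confusion counts.
#' @param nOverride fixed ensemble size (e.g. 1 for the unsplit baseline).
#' @return a \linkS4class{CVReport}.
#' @export
crossValidate <- function(mm, learner = xgbLearner(), k = 5L,
                          rounds = 10L, seed = 1L, threshold = 0.5,
                          nOverride = NULL) {
  y <- modelLabels(mm)
  genes <- names(y)
  probs <- matrix(NA_real_, length(genes), rounds,
                  dimnames = list(genes, paste0("round", seq_len(rounds))))
  foldList <- vector("list", rounds)
  confusion <- data.frame()
  metricsByRound <- data.frame()
  for (r in seq_len(rounds)) {
    rseed <- .deriveSeed(seed, r)
    folds <- stratifiedFolds(y, k, seed = rseed)
    foldList[[r]] <- folds
    for (f in seq_len(k)) {
      testGenes <- genes[folds == f]
      trainGenes <- genes[folds != f]
      prep <- .preprocess(mm, trainGenes)
      x <- modelFeatures(prep)
      model <- tryCatch(
        sveFit(x[trainGenes, , drop = FALSE], y[trainGenes],
               learner = learner, seed = .deriveSeed(rseed, f),
               nOverride = nOverride),
        error = function(e) stop(sprintf("round %d fold %d: %s",
                                         r, f, conditionMessage(e))))
      probs[testGenes, r] <-
        svePredictProba(model, x[testGenes, , drop = FALSE])
    }
    pred <- as.integer(probs[, r] >= threshold)
    tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
    tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
    confusion <- rbind(confusion,
                       data.frame(round = r, tp = tp, fp = fp,
                                  tn = tn, fn = fn))
    metricsByRound <- rbind(
      metricsByRound,
      as.data.frame(as.list(metricsPanel(tp, fp, tn, fn,
                                         probs = probs[, r], truth = y))))
  }
  rownames(metricsByRound) <- NULL
  new("CVReport", confusion = confusion, metricsByRound = metricsByRound,
      probs = probs, truth = y, folds = foldList, k = as.integer(k),
      rounds = as.integer(rounds), threshold = threshold)
}

#' @describeIn crossValidate metric summary: mean and sd over rounds.
#' @param report a \code{CVReport}.
#' @export
cvMetrics <- function(report) {
  m <- report@metricsByRound
  data.frame(metric = colnames(m),
             mean = vapply(m, mean, 0, na.rm = TRUE),
             sd = vapply(m, sd, 0, na.rm = TRUE),
             row.names = NULL)
}

#' @describeIn crossValidate per-round pooled confusion counts.
#' @export
cvConfusion <- function(report) report@confusion

#' @describeIn crossValidate per-gene mean and sd of the held-out
#'   probability over rounds, with the hard label at the report threshold.
#' @export
perGeneProbabilities <- function(report) {
  data.frame(
    gene = rownames(report@probs),
    truth = unname(report@truth),
    prob_mean = rowMeans(report@probs),
    prob_sd = apply(report@probs, 1L, sd),
    label = ifelse(rowMeans(report@probs) >= report@threshold, 1L, 0L),
    row.names = NULL)
}

#' True positive rate on a gene subset
#'
#' Fraction of the subset's genes whose held-out prediction in one round is
#' the positive class. Genes absent from the evaluated matrix (e.g. no
#' attributes were retrieved for them) are excluded from the denominator
#' and reported.
#'
#' @param report a \linkS4class{CVReport}.
#' @param subset character vector of gene ids (e.g. uncommon
#'   context-specific essential genes).
#' @param round which round's predictions to use (default 1).
#' @return list with \code{tpr} (chosen round), \code{tprMean} (mean over
#'   all rounds) and \code{excluded} (genes not in the report).
#' @export
subsetTPR <- function(report, subset, round = 1L) {
  present <- intersect(subset, rownames(report@probs))
  excluded <- setdiff(subset, present)
  if (!length(present)) stop("no subset gene was predicted")
  if (length(excluded))
    .logLine("subsetTPR: excluded ", length(excluded),
             " gene(s) absent from the evaluated matrix: ",
             paste(excluded, collapse = ", "))
  hit <- report@probs[present, , drop = FALSE] >= report@threshold
  list(tpr = mean(hit[, round]),
       tprMean = mean(colMeans(hit)),
       excluded = excluded)
}

#' Write a CV report to CSV
#' @param report a \linkS4class{CVReport}.
#' @param metricsPath,genesPath output files for the metric summary and the
#'   per-gene table (either may be \code{NULL} to skip).
#' @export
writeCVReport <- function(report, metricsPath = NULL, genesPath = NULL) {
  if (!is.null(metricsPath))
    write.csv(format(cvMetrics(report), digits = 15), metricsPath,
              row.names = FALSE, quote = FALSE)
  if (!is.null(genesPath))
    write.csv(format(perGeneProbabilities(report), digits = 15), genesPath,
              row.names = FALSE, quote = FALSE)
  invisible(report)
}

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d-fold x %d round(s), %d genes (%d positive)\n",
              object@k, object@rounds, length(object@truth),
              sum(object@truth)))
  m <- cvMetrics(object)
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m$metric[i], m$mean[i], m$sd[i]))
})
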