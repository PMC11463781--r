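test_that("stratified folds balance sizes and positives", {
  y <- setNames(c(rep(1L, 7), rep(0L, 93)), sprintf("g%03d", 1:100))
  f <- stratifiedFolds(y, k = 5, seed = 1)
  expect_setequal(names(f), names(y))
  sizes <- table(f)
  expect_lte(max(sizes) - min(sizes), 1)
  pos <- table(f[y == 1L])
  expect_lte(max(pos) - min(pos), 1)
  expect_identical(f, stratifiedFolds(y, k = 5, seed = 1))
  expect_false(identical(f, stratifiedFolds(y, k = 5, seed = 2)))
  expect_error(stratifiedFolds(y[1:10], k = 5), "at least k")
})

test_that("the metric panel matches closed forms and the pair-count AUC", {
  m <- metricsPanel(tp = 9, fn = 1, tn = 80, fp = 10)
  expect_equal(unname(round(m["Sensitivity"], 3)), 0.900)
  expect_equal(unname(round(m["Specificity"], 3)), 0.889)
  expect_equal(unname(round(m["BA"], 3)), 0.894)
  perfect <- metricsPanel(tp = 10, fn = 0, tn = 90, fp = 0,
                          probs = c(rep(0.9, 10), rep(0.1, 90)),
                          truth = c(rep(1, 10), rep(0, 90)))
  expect_equal(unname(perfect[c("BA", "MCC", "AUC")]), c(1, 1, 1))
  # degenerate MCC denominator -> NA, not zero
  expect_true(is.na(metricsPanel(tp = 0, fn = 0, tn = 5, fp = 5)["MCC"]))
  # AUC identities and tie handling against the brute-force oracle
  expect_equal(rocAUC(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  set.seed(8)
  for (i in 1:10) {
    p <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)  # many ties
    tr <- rbinom(40, 1, 0.3)
    if (sum(tr) %in% c(0, 40)) next
    expect_equal(rocAUC(p, tr), aucPairOracle(p, tr))
  }
})

test_that("rank AUC agrees with an established implementation", {
  set.seed(13)
  p <- runif(60)
  tr <- rbinom(60, 1, 0.25)
  auc <- suppressMessages(as.numeric(pROC::auc(tr, p, direction = "<")))
  expect_equal(rocAUC(p, tr), auc)
})

test_that("BA is invariant under class swap with metric swap", {
  m <- metricsPanel(tp = 12, fn = 3, tn = 40, fp = 9)
  mSwap <- metricsPanel(tp = 40, fn = 9, tn = 12, fp = 3)
  expect_equal(unname(m["Sensitivity"]), unname(mSwap["Specificity"]))
  expect_equal(unname(m["BA"]), unname(mSwap["BA"]))
})

mkReport <- function(rounds = 3, n = 150, frac = 0.1, effect = 2.5,
                     seed = 5) {
  y <- setNames(as.integer(seq_len(n) <= round(frac * n)),
                sprintf("g%04d", seq_len(n)))
  ft <- syntheticFeatures(y, nBio = 6, effectSize = effect, seed = seed)
  lab <- setNames(ifelse(y == 1, "E", "NE"), names(y))
  mm <- assembleModelMatrix(ft, lab)
  crossValidate(mm, learner = centroidLearner(), k = 5, rounds = rounds,
                seed = seed)
}

test_that("every gene is predicted exactly once per round", {
  rep <- mkReport(rounds = 3)
  expect_false(anyNA(rep@probs))
  expect_equal(ncol(rep@probs), 3L)
  for (r in seq_along(rep@folds)) {
    f <- rep@folds[[r]]
    expect_setequal(names(f), rownames(rep@probs))   # folds cover universe
    expect_lte(max(table(f[rep@truth == 1L])) -
                 min(table(f[rep@truth == 1L])), 1)
  }
})

test_that("report metrics recompute exactly from the stored confusions", {
  rep <- mkReport(rounds = 3)
  conf <- cvConfusion(rep)
  for (r in seq_len(nrow(conf))) {
    m <- metricsPanel(conf$tp[r], conf$fp[r], conf$tn[r], conf$fn[r],
                      probs = rep@probs[, r], truth = rep@truth)
    expect_equal(unname(m),
                 unname(unlist(rep@metricsByRound[r, names(m)])))
  }
  agg <- cvMetrics(rep)
  expect_equal(agg$mean[agg$metric == "BA"], mean(rep@metricsByRound$BA))
  expect_equal(agg$sd[agg$metric == "AUC"], sd(rep@metricsByRound$AUC))
})

test_that("a separable problem reaches BA 1 in a single round", {
  rep <- mkReport(rounds = 1, effect = 8)
  expect_equal(rep@metricsByRound$BA, 1)
})

test_that("per-gene summaries and report files are consistent", {
  rep <- mkReport(rounds = 2)
  pg <- perGeneProbabilities(rep)
  expect_equal(pg$prob_mean, unname(rowMeans(rep@probs)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeCVReport(rep, f1, f2)
  back <- read.csv(f1)
  expect_equal(back$mean[back$metric == "BA"],
               cvMetrics(rep)$mean[cvMetrics(rep)$metric == "BA"],
               tolerance = 1e-12)
})

test_that("subset TPR matches sensitivity on the full positive set", {
  rep <- mkReport(rounds = 2)
  posGenes <- names(rep@truth)[rep@truth == 1L]
  res <- subsetTPR(rep, posGenes, round = 1L)
  conf <- cvConfusion(rep)
  expect_equal(res$tpr, conf$tp[1] / (conf$tp[1] + conf$fn[1]))
  # absent genes excluded from the denominator and reported
  expect_message(res2 <- subsetTPR(rep, c(posGenes, "ghost"), round = 1L),
                 "ghost")
  expect_equal(res2$tpr, res$tpr)
  expect_identical(res2$excluded, "ghost")
  expect_error(subsetTPR(rep, "ghost"), "no subset gene")
})
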