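# Independent oracles used to cross-check the implementation.

# Exhaustive threshold scan: evaluates the between-class variance directly on
# the values at every midpoint between consecutive sorted distinct values.
otsuScanOracle <- function(values) {
  v <- sort(values[is.finite(values)])
  u <- unique(v)
  mids <- (u[-length(u)] + u[-1L]) / 2
  n <- length(v)
  best <- -Inf
  bestT <- NA_real_
  for (t in mids) {
    lo <- v[v < t]
    hi <- v[v >= t]
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best) {
      best <- bcv
      bestT <- t
    }
  }
  bestT
}

# Brute-force AUC: fraction of (positive, negative) pairs ranked correctly,
# ties counted half.
aucPairOracle <- function(probs, truth) {
  pos <- probs[truth == 1]
  neg <- probs[truth == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# Normalised second-order walk transition law P(next | prev, cur) for a
# weighted graph given return parameter p and in-out parameter q.
secondOrderOracle <- function(edges, p, q) {
  nodes <- sort(unique(c(edges$node1, edges$node2)))
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    w[edges$node1[i], edges$node2[i]] <- edges$weight[i]
    w[edges$node2[i], edges$node1[i]] <- edges$weight[i]
  }
  trans <- list()
  for (prev in nodes) for (cur in nodes) {
    if (w[prev, cur] == 0) next
    nbr <- nodes[w[cur, ] > 0]
    bias <- vapply(nbr, function(x) {
      if (x == prev) w[cur, x] / p
      else if (w[prev, x] > 0) w[cur, x]
      else w[cur, x] / q
    }, 0)
    trans[[paste(prev, cur, sep = "->")]] <- bias / sum(bias)
  }
  trans
}

# Count empirical (prev, cur) -> next transition frequencies in a walk list.
countTransitions <- function(walks) {
  counts <- new.env()
  for (wk in walks) {
    if (length(wk) < 3L) next
    for (i in 3:length(wk)) {
      key <- paste(wk[i - 2L], wk[i - 1L], sep = "->")
      tab <- counts[[key]]
      if (is.null(tab)) tab <- integer()
      prev <- tab[wk[i]]
      tab[wk[i]] <- if (length(prev) == 0L || is.na(prev)) 1L else prev + 1L
      counts[[key]] <- tab
    }
  }
  as.list(counts)
}

# A tiny screen whose columns have two well-separated clusters, so every
# Otsu threshold falls in the gap and per-cell-line labels are controlled
# directly: TRUE in `lowMask` means "draw this (gene, cell) score from the
# low cluster". Two anchor genes (one per cluster) keep every column
# bimodal even when all assayed genes share a cluster.
screenFromMask <- function(lowMask, contexts) {
  lowMask <- rbind(lowMask,
                   anchorLow. = rep(TRUE, ncol(lowMask)),
                   anchorHigh. = rep(FALSE, ncol(lowMask)))
  low <- -3 + seq_len(length(lowMask)) * 1e-3
  high <- 0 + seq_len(length(lowMask)) * 1e-3
  m <- matrix(ifelse(lowMask, low, high), nrow(lowMask), ncol(lowMask),
              dimnames = dimnames(lowMask))
  ScoreScreen(m, contexts)
}

# Deterministic, row-order-independent base learner: nearest-centroid with a
# logistic link on the distance difference. Used where exact reproducibility
# of a reference fit matters.
centroidLearner <- function() {
  list(
    name = "centroid",
    fit = function(x, y) {
      list(mu1 = colMeans(x[y == 1, , drop = FALSE]),
           mu0 = colMeans(x[y == 0, , drop = FALSE]))
    },
    predict = function(model, x) {
      d1 <- sqrt(rowSums(sweep(x, 2L, model$mu1)^2))
      d0 <- sqrt(rowSums(sweep(x, 2L, model$mu0)^2))
      1 / (1 + exp(d1 - d0))
    }
  )
}

# Stub learner predicting the training minority prevalence of its member.
prevalenceLearner <- function() {
  list(
    name = "prevalence",
    fit = function(x, y) list(mu = mean(y)),
    predict = function(model, x) rep(model$mu, nrow(x))
  )
}

# An SVEModel whose members return fixed probabilities, for checking the
# soft-vote aggregation against an independent mean.
fixedVoteModel <- function(values, featureNames) {
  majRows <- sprintf("maj%02d", seq_len(2L * length(values)))
  new("SVEModel",
      members = lapply(values, function(v) list(v = v)),
      sliceAssignment = setNames(rep_len(seq_along(values),
                                         length(majRows)), majRows),
      n = length(values),
      learner = list(name = "fixed",
                     predict = function(m, x) rep(m$v, nrow(x))),
      featureNames = featureNames,
      classes = c("1", "0"))
}
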