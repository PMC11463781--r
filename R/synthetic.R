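#' Synthetic CRISPR screen with planted essentiality
#'
#' Emulates a gene-effect screen: per cell line, essential genes draw scores
#' from a low (negative) Normal mode and not-essential genes from a mode
#' near zero, giving the bimodal per-cell-line distribution the labelling
#' stage thresholds. A core of essential genes is shared by every context
#' and each context additionally gets a private essential set, so the
#' common/context subtraction has a known answer. Entries go missing
#' uniformly at rate \code{missingFrac}. Defaults mirror the study
#' conditions: ~7\% essential prevalence, well-separated modes, three
#' contexts of unequal size.
#'
#' @param nGenes number of genes (default 3000).
#' @param contexts named integer vector: cell lines per context.
#' @param eFraction essential prevalence per context (default 0.07).
#' @param privateFraction fraction of each context's essential set that is
#'   private to it (default 0.2).
#' @param eDist,neDist \code{c(mean, sd)} of the essential / not-essential
#'   score modes.
#' @param missingFrac uniform missing-entry rate (default 0.05).
#' @param aeLayer optional \code{list(fraction, mean, sd)}: a slice of the
#'   not-essential genes drawn from an intermediate mode in every context
#'   (the almost-essential layer for the three-class refinement).
#' @param seed RNG seed; generation is bit-reproducible.
#' @return list with \code{screen} (a \code{\link{ScoreScreen}}
#'   SummarizedExperiment) and \code{truth}: \code{perContext} (planted
#'   essential set per context), \code{common} (core set), \code{private}
#'   (per-context private sets), \code{aE} (intermediate-layer genes, if
#'   any).
#' @export
syntheticScores <- function(nGenes = 3000L,
                            contexts = c(ctxA = 30L, ctxB = 20L,
                                         ctxC = 10L),
                            eFraction = 0.07, privateFraction = 0.2,
                            eDist = c(-1.5, 0.3), neDist = c(0, 0.2),
                            missingFrac = 0.05, aeLayer = NULL,
                            seed = 1L) {
  stopifnot(eFraction > 0, eFraction < 1, privateFraction >= 0,
            privateFraction <= 1, eDist[1L] < neDist[1L],
            missingFrac >= 0, missingFrac < 1)
  genes <- sprintf("G%05d", seq_len(nGenes))
  nE <- round(eFraction * nGenes)
  nPriv <- round(privateFraction * nE)
  nCore <- nE - nPriv
  .withSeed(seed, {
    core <- genes[seq_len(nCore)]
    pool <- genes[(nCore + 1L):nGenes]
    private <- list()
    for (cc in names(contexts)) {
      private[[cc]] <- pool[seq_len(nPriv)]
      pool <- pool[-seq_len(nPriv)]
    }
    aeGenes <- character(0)
    if (!is.null(aeLayer)) {
      nAE <- round(aeLayer$fraction * nGenes)
      aeGenes <- pool[seq_len(min(nAE, length(pool)))]
    }
    cells <- character(0)
    ctxMap <- character(0)
    for (cc in names(contexts)) {
      ids <- sprintf("%s_cl%02d", cc, seq_len(contexts[[cc]]))
      cells <- c(cells, ids)
      ctxMap <- c(ctxMap, setNames(rep(cc, length(ids)), ids))
    }
    m <- matrix(NA_real_, nGenes, length(cells),
                dimnames = list(genes, cells))
    for (cc in names(contexts)) {
      eSet <- c(core, private[[cc]])
      isE <- genes %in% eSet
      isAE <- genes %in% aeGenes
      for (cell in names(ctxMap)[ctxMap == cc]) {
        v <- rnorm(nGenes, neDist[1L], neDist[2L])
        v[isE] <- rnorm(sum(isE), eDist[1L], eDist[2L])
        if (any(isAE))
          v[isAE] <- rnorm(sum(isAE), aeLayer$mean, aeLayer$sd)
        m[, cell] <- v
      }
    }
    if (missingFrac > 0)
      m[runif(length(m)) < missingFrac] <- NA_real_
    perContext <- lapply(private, function(p) sort(c(core, p)))
    list(screen = ScoreScreen(m, ctxMap),
         truth = list(perContext = perContext, common = sort(core),
                      private = lapply(private, sort),
                      aE = sort(aeGenes)))
  })
}

#' Synthetic planted-partition interaction graph
#'
#' Nodes split into equal blocks; an edge appears within a block with
#' probability \code{pIn} and between blocks with \code{pOut}, carrying a
#' confidence weight drawn from Uniform(0.5, 1), i.e. already above the
#' usual combined-score filter.
#'
#' @param nBlocks,blockSize community structure (default 2 x 50).
#' @param pIn,pOut within-/between-block edge probabilities.
#' @param seed RNG seed.
#' @param nodeNames optional node id vector (default \code{N001 ...}).
#' @return list with \code{edges} (canonical edge data.frame) and
#'   \code{blocks} (named integer block membership).
#' @export
syntheticGraph <- function(nBlocks = 2L, blockSize = 50L, pIn = 0.3,
                           pOut = 0.01, seed = 1L, nodeNames = NULL) {
  stopifnot(pIn > pOut, pIn <= 1, pOut >= 0)
  n <- nBlocks * blockSize
  ids <- if (is.null(nodeNames)) sprintf("N%04d", seq_len(n)) else nodeNames
  stopifnot(length(ids) == n)
  blocks <- setNames(rep(seq_len(nBlocks), each = blockSize), ids)
  .withSeed(seed, {
    pairs <- utils::combn(n, 2L)
    same <- blocks[pairs[1L, ]] == blocks[pairs[2L, ]]
    prob <- ifelse(same, pIn, pOut)
    keep <- runif(ncol(pairs)) < prob
    edges <- data.frame(node1 = ids[pairs[1L, keep]],
                        node2 = ids[pairs[2L, keep]],
                        weight = runif(sum(keep), 0.5, 1),
                        stringsAsFactors = FALSE)
    list(edges = edgeList(edges), blocks = blocks)
  })
}

#' Synthetic gene feature tables with class-separable columns
#'
#' Class-conditional Gaussian features: a fraction of columns is shifted by
#' \code{effectSize} for the positive class, the rest is pure noise; a
#' given number of constant columns is injected to exercise the constant
#' filter. With \code{effectSize = 0} the features carry no signal (the
#' null model).
#'
#' @param labels named 0/1 integer vector (or a
#'   \linkS4class{LabelAssignment}; its essential class becomes 1).
#' @param nBio,nCC number of Bio / CCcfs columns.
#' @param effectSize mean shift of the positive class on informative
#'   columns, in sd units.
#' @param shiftFraction fraction of columns that are informative.
#' @param nConstant constant columns appended to the Bio table.
#' @param missingFrac uniform missing rate across feature cells.
#' @param seed RNG seed.
#' @return list of \linkS4class{FeatureTable}s (Bio always; CCcfs when
#'   \code{nCC > 0}).
#' @export
syntheticFeatures <- function(labels, nBio = 20L, nCC = 0L,
                              effectSize = 2, shiftFraction = 0.5,
                              nConstant = 0L, missingFrac = 0,
                              seed = 1L) {
  stopifnot(effectSize >= 0)
  if (is(labels, "LabelAssignment")) {
    lab <- geneLabels(labels)
    labels <- setNames(as.integer(lab == "E"), names(lab))
  }
  genes <- names(labels)
  gen <- function(nCols, prefix) {
    nShift <- round(shiftFraction * nCols)
    m <- matrix(rnorm(length(genes) * nCols), length(genes), nCols,
                dimnames = list(genes, paste0(prefix, seq_len(nCols))))
    if (nShift > 0)
      m[, seq_len(nShift)] <- m[, seq_len(nShift), drop = FALSE] +
        effectSize * labels
    if (missingFrac > 0)
      m[runif(length(m)) < missingFrac] <- NA_real_
    m
  }
  .withSeed(seed, {
    bio <- gen(nBio, "bio_")
    if (nConstant > 0L) {
      const <- matrix(1, length(genes), nConstant,
                      dimnames = list(genes,
                                      paste0("bio_const_",
                                             seq_len(nConstant))))
      bio <- cbind(bio, const)
    }
    out <- list(FeatureTable(bio, "Bio"))
    if (nCC > 0L) out <- c(out, list(FeatureTable(gen(nCC, "cc_"), "CCcfs")))
    out
  })
}
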