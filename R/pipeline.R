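#' Default pipeline configuration
#'
#' Returns a configuration list for \code{\link{runPipeline}}. With no input
#' paths the pipeline starts from its own synthetic stage, so the whole
#' chain (label, embed, assemble, cross-validate) runs self-contained. Every
#' source of randomness derives from \code{seed}.
#'
#' @param outDir artifact directory (created if needed).
#' @param seed run-level seed, recorded in the log.
#' @param scoresPath,contextsPath,edgesPath,featurePaths optional input
#'   files; \code{featurePaths} is a named character vector
#'   (name = group tag). When \code{NULL}, synthetic inputs are generated.
#' @param context which context to cross-validate (default: first).
#' @param synth parameters forwarded to the synthetic generators
#'   (\code{nGenes}, \code{contexts}, \code{nBlocks}, \code{blockSize},
#'   \code{pIn}, \code{pOut}, \code{nBio}, \code{effectSize}).
#' @param labelling \code{minCellLines}, \code{maxMissingFrac},
#'   \code{threeClass} flag.
#' @param embedding arguments for \code{\link{walkConfig}} (e.g.
#'   \code{dimensions}).
#' @param minScore edge confidence filter.
#' @param groups feature groups used by the model.
#' @param cv \code{k} and \code{rounds}.
#' @return a \code{RunConfig}-style list.
#' @export
pipelineConfig <- function(outDir, seed = 1L,
                           scoresPath = NULL, contextsPath = NULL,
                           edgesPath = NULL, featurePaths = NULL,
                           context = NULL,
                           synth = list(), labelling = list(),
                           embedding = list(), minScore = 0.5,
                           groups = c("Bio", "N2V"),
                           cv = list(k = 5L, rounds = 3L)) {
  synthDefaults <- list(nGenes = 600L, contexts = c(ctxA = 15L, ctxB = 12L),
                        nBlocks = 2L, blockSize = NULL, pIn = 0.1,
                        pOut = 0.01, nBio = 20L, effectSize = 2)
  labDefaults <- list(minCellLines = 10L, maxMissingFrac = 0.95,
                      threeClass = FALSE)
  embDefaults <- list(dimensions = 32L)
  cfg <- list(outDir = outDir, seed = as.integer(seed),
              scoresPath = scoresPath, contextsPath = contextsPath,
              edgesPath = edgesPath, featurePaths = featurePaths,
              context = context,
              synth = utils::modifyList(synthDefaults, synth),
              labelling = utils::modifyList(labDefaults, labelling),
              embedding = utils::modifyList(embDefaults, embedding),
              minScore = minScore, groups = groups,
              cv = utils::modifyList(list(k = 5L, rounds = 3L), cv))
  cfg
}

.manifestPath <- function(outDir) file.path(outDir, "manifest.csv")

.readManifest <- function(outDir) {
  p <- .manifestPath(outDir)
  if (file.exists(p)) read.csv(p, colClasses = "character")
  else data.frame(stage = character(), file = character(),
                  role = character(), md5 = character())
}

.hashFiles <- function(paths) {
  h <- as.character(tools::md5sum(paths))
  h[is.na(h)] <- "missing"
  h
}

# A stage is current when all its recorded input and output hashes match the
# files on disk; otherwise it reruns (a corrupted artifact changes its hash).
.stageCurrent <- function(manifest, stage, inputs, outputs) {
  rec <- manifest[manifest$stage == stage, , drop = FALSE]
  want <- c(inputs, outputs)
  if (nrow(rec) == 0L || !setequal(rec$file, want)) return(FALSE)
  all(.hashFiles(rec$file) == rec$md5)
}

.recordStage <- function(outDir, stage, inputs, outputs) {
  manifest <- .readManifest(outDir)
  manifest <- manifest[manifest$stage != stage, , drop = FALSE]
  files <- c(inputs, outputs)
  add <- data.frame(stage = stage, file = files,
                    role = c(rep("input", length(inputs)),
                             rep("output", length(outputs))),
                    md5 = .hashFiles(files))
  write.csv(rbind(manifest, add), .manifestPath(outDir), row.names = FALSE)
}

.runStage <- function(outDir, stage, inputs, outputs, body) {
  manifest <- .readManifest(outDir)
  if (.stageCurrent(manifest, stage, inputs, outputs)) {
    .logLine("pipeline: stage '", stage, "' up to date, skipping")
    return(invisible(FALSE))
  }
  if (any(file.exists(outputs)) &&
      nrow(manifest[manifest$stage == stage, ]) > 0L)
    .logLine("pipeline: stage '", stage,
             "' artifacts stale or corrupted, re-executing")
  withCallingHandlers(body(),
    error = function(e) stop(sprintf("pipeline stage '%s' failed: %s",
                                     stage, conditionMessage(e))))
  .recordStage(outDir, stage, inputs, outputs)
  invisible(TRUE)
}

#' Run the full labelling-and-prediction pipeline
#'
#' Stages, each resumable from its on-disk artifact (skipped when the
#' manifest hashes of its inputs and outputs still match): \code{synth}
#' (only when no input paths are given), \code{label}, \code{embed},
#' \code{evaluate}. Artifacts are plain CSV/TSV. Two runs with the same
#' config and seed produce byte-identical label files and identical metric
#' tables.
#'
#' @param cfg a \code{\link{pipelineConfig}} list.
#' @return invisibly, a list of artifact paths.
#' @export
runPipeline <- function(cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$outDir, "run.log")
  oldOpt <- options(crisprEssentials.log = logPath)
  on.exit(options(oldOpt), add = TRUE)
  .logLine("pipeline: seed = ", cfg$seed)

  paths <- list(
    scores = cfg$scoresPath, contexts = cfg$contextsPath,
    edges = cfg$edgesPath, features = cfg$featurePaths)

  # -- stage synth ---------------------------------------------------------
  if (is.null(paths$scores)) {
    paths$scores <- file.path(cfg$outDir, "scores.csv")
    paths$contexts <- file.path(cfg$outDir, "contexts.csv")
    paths$edges <- file.path(cfg$outDir, "edges.tsv")
    paths$features <- c(Bio = file.path(cfg$outDir, "features_bio.csv"))
    truthPath <- file.path(cfg$outDir, "truth_private.csv")
    .runStage(cfg$outDir, "synth", character(0),
              c(paths$scores, paths$contexts, paths$edges,
                unname(paths$features), truthPath), function() {
      syn <- syntheticScores(
        nGenes = cfg$synth$nGenes, contexts = cfg$synth$contexts,
        seed = .deriveSeed(cfg$seed, 11L))
      m <- effectScores(syn$screen)
      write.csv(data.frame(gene = rownames(m), round(m, 6),
                           check.names = FALSE),
                paths$scores, row.names = FALSE, quote = FALSE)
      write.csv(data.frame(cell_id = colnames(m),
                           context = unname(cellContexts(syn$screen))),
                paths$contexts, row.names = FALSE, quote = FALSE)
      bs <- cfg$synth$blockSize
      if (is.null(bs)) bs <- cfg$synth$nGenes %/% cfg$synth$nBlocks
      gr <- syntheticGraph(
        nBlocks = cfg$synth$nBlocks, blockSize = bs,
        pIn = cfg$synth$pIn, pOut = cfg$synth$pOut,
        seed = .deriveSeed(cfg$seed, 12L),
        nodeNames = rownames(m)[seq_len(cfg$synth$nBlocks * bs)])
      write.table(gr$edges, paths$edges, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      ctx1 <- names(cfg$synth$contexts)[1L]
      truthLab <- setNames(
        as.integer(rownames(m) %in% syn$truth$perContext[[ctx1]]),
        rownames(m))
      feats <- syntheticFeatures(
        truthLab, nBio = cfg$synth$nBio,
        effectSize = cfg$synth$effectSize,
        seed = .deriveSeed(cfg$seed, 13L))
      fv <- featureValues(feats[[1L]])
      write.csv(data.frame(gene = rownames(fv), round(fv, 6),
                           check.names = FALSE),
                paths$features[["Bio"]], row.names = FALSE, quote = FALSE)
      priv <- do.call(rbind, lapply(names(syn$truth$private), function(cc)
        data.frame(context = cc, gene = syn$truth$private[[cc]])))
      write.csv(priv, truthPath, row.names = FALSE, quote = FALSE)
    })
  }

  # -- stage label ---------------------------------------------------------
  scores <- readScoreMatrix(paths$scores, orientation = "genes-in-rows")
  contexts <- readContextMap(paths$contexts)
  screen <- filterScreen(ScoreScreen(scores, contexts),
                         minCellLines = cfg$labelling$minCellLines,
                         maxMissingFrac = cfg$labelling$maxMissingFrac)
  ctxs <- contextNames(screen)
  labelFiles <- c(file.path(cfg$outDir,
                            paste0("labels_", ctxs, ".csv")),
                  file.path(cfg$outDir, "labels_common.csv"))
  thrFiles <- file.path(cfg$outDir, paste0("thresholds_", ctxs, ".csv"))
  ucsFiles <- file.path(cfg$outDir, paste0("ucs_", ctxs, ".txt"))
  .runStage(cfg$outDir, "label",
            c(paths$scores, paths$contexts),
            c(labelFiles, thrFiles, ucsFiles), function() {
    perCtx <- lapply(setNames(ctxs, ctxs),
                     function(cc) labelContext(screen, cc))
    common <- labelCommon(screen, perCtx)
    for (i in seq_along(ctxs)) {
      cc <- ctxs[i]
      asg <- if (isTRUE(cfg$labelling$threeClass))
        labelThreeClass(screen, cc, perCtx[[cc]]) else perCtx[[cc]]
      writeLabels(asg, labelFiles[i])
      write.csv(cellThresholds(perCtx[[cc]]), thrFiles[i],
                row.names = FALSE, quote = FALSE)
      writeLines(ucsGenes(perCtx[[cc]], common), ucsFiles[i])
    }
    writeLabels(common, labelFiles[length(labelFiles)])
  })

  # -- stage embed ---------------------------------------------------------
  embPath <- file.path(cfg$outDir, "embedding.csv")
  .runStage(cfg$outDir, "embed", paths$edges, embPath, function() {
    edges <- readEdgeList(paths$edges, minScore = cfg$minScore)
    wc <- do.call(walkConfig,
                  c(cfg$embedding,
                    list(seed = .deriveSeed(cfg$seed, 21L))))
    writeEmbedding(embedNodes(edges, wc), embPath)
  })

  # -- stage evaluate ------------------------------------------------------
  context <- if (is.null(cfg$context)) ctxs[1L] else cfg$context
  metricsPath <- file.path(cfg$outDir, "cv_metrics.csv")
  genesPath <- file.path(cfg$outDir, "cv_genes.csv")
  .runStage(cfg$outDir, "evaluate",
            c(labelFiles, embPath, unname(paths$features)),
            c(metricsPath, genesPath), function() {
    labels <- readLabels(file.path(cfg$outDir,
                                   paste0("labels_", context, ".csv")))
    tables <- lapply(names(paths$features), function(g)
      readFeatureTable(paths$features[[g]], g))
    if ("N2V" %in% cfg$groups)
      tables <- c(tables, list(FeatureTable(readEmbedding(embPath),
                                            "N2V")))
    mm <- assembleModelMatrix(tables, labels, groups = cfg$groups)
    report <- crossValidate(mm, k = cfg$cv$k, rounds = cfg$cv$rounds,
                            seed = .deriveSeed(cfg$seed, 31L))
    writeCVReport(report, metricsPath, genesPath)
  })

  invisible(list(labels = labelFiles, thresholds = thrFiles,
                 ucs = ucsFiles, embedding = embPath,
                 metrics = metricsPath, genes = genesPath,
                 log = logPath, manifest = .manifestPath(cfg$outDir)))
}
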