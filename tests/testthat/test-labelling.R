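test_that("otsu threshold separates well-separated modes", {
  v <- c(-3.0, -2.9, -2.8, 0.0, 0.1, 0.2)
  t1 <- otsuThreshold(v)
  expect_gt(t1, -2.8)
  expect_lt(t1, 0.0)
  # two-point input: forced separation
  t2 <- otsuThreshold(c(-1, 0))
  expect_gt(t2, -1)
  expect_lte(t2, 0)
  expect_error(otsuThreshold(c(1, 1, 1)), "identical")
  expect_error(otsuThreshold(2), "two finite")
})

test_that("otsu matches the exhaustive midpoint-scan oracle", {
  v <- c(-3.0, -2.8, -2.9, 0.1, 0.2, 0.0, 0.15, 0.05)
  tHist <- otsuThreshold(v)
  tScan <- otsuScanOracle(v)
  binw <- (max(v) - min(v)) / 256
  expect_lt(abs(sum(v < tHist) - sum(v < tScan)), 1)  # same partition
  # property over random mixed inputs: identical E/NE partition up to values
  # within one bin width of the scan threshold
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:400, 1)
    v <- if (i %% 2 == 0) {
      c(rnorm(round(n * 0.1), -1.5, 0.3), rnorm(n, 0, 0.2))
    } else {
      rnorm(n, 0, 1)
    }
    tHist <- otsuThreshold(v)
    tScan <- otsuScanOracle(v)
    binw <- (max(v) - min(v)) / 256
    disagree <- v[(v < tHist) != (v < tScan)]
    expect_true(all(abs(disagree - tScan) <= binw))
  }
})

test_that("binarisation labels below-threshold E, at/above NE, missing NA", {
  col <- c(g1 = -2.5, g2 = -1.0, g3 = 0.2, g4 = NA, g5 = 0.1)
  b <- binariseCellLine(col, "cellX")
  thr <- b$threshold$threshold
  expect_equal(unname(b$labels["g1"]), "E")      # -2.5 < threshold
  expect_true(is.na(b$labels["g4"]))
  expect_identical(unname(b$labels[c("g3", "g5")]), c("NE", "NE"))
  expect_gt(thr, min(col, na.rm = TRUE))
  expect_lt(thr, max(col, na.rm = TRUE))
  expect_equal(b$threshold$n_used, 4L)
  # a score exactly at the threshold is NE
  lab <- ifelse(col[!is.na(col)] < thr, "E", "NE")
  atThr <- c(col[!is.na(col)], gx = thr)
  expect_equal(unname(ifelse(atThr["gx"] < thr, "E", "NE")), "NE")
  # constant column: all NE with a logged warning
  expect_message(bc <- binariseCellLine(c(a = 1, b = 1, c = 1), "flat"),
                 "constant")
  expect_true(all(bc$labels == "NE"))
})

test_that("context labels are the tie-broken mode of cell-line labels", {
  genes <- paste0("g", 1:4)
  cells <- paste0("c", 1:4)
  # rows: g1 E in 2/4 (tie -> NE), g2 E in 3/4 (E), g3 all E, g4 all NE
  mask <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                c(TRUE, TRUE, TRUE, FALSE),
                c(TRUE, TRUE, TRUE, TRUE),
                c(FALSE, FALSE, FALSE, FALSE))
  dimnames(mask) <- list(genes, cells)
  scr <- screenFromMask(mask, setNames(rep("t1", 4), cells))
  asg <- labelContext(scr, "t1")
  expect_identical(unname(geneLabels(asg)[genes]),
                   c("NE", "E", "E", "NE"))
  expect_error(labelContext(scr, "nope"), "unknown context")
  # single cell line: mode of one
  scr1 <- screenFromMask(mask[, 1, drop = FALSE],
                         setNames("t1", "c1"))
  expect_identical(unname(geneLabels(labelContext(scr1, "t1"))[1:2]),
                   c("E", "E"))
})

test_that("genes without usable scores are omitted and logged", {
  m <- matrix(c(-3, 0, NA, -3.1, 0.1, NA, -2.9, 0.2, NA, -3, 0.1, NA),
              3, 4, dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  scr <- ScoreScreen(m, setNames(rep("t1", 4), colnames(m)))
  expect_message(asg <- labelContext(scr, "t1"), "omitted 1")
  expect_identical(sort(names(geneLabels(asg))), c("g1", "g2"))
})

test_that("common labels use a two-level mode immune to context size", {
  genes <- paste0("g", 1:3)
  # context A: 4 cells, context B: 1 cell
  cells <- c(paste0("a", 1:4), "b1")
  ctx <- setNames(c(rep("A", 4), "B"), cells)
  # g1: E in A, NE in B -> context labels (E, NE) -> tie -> NE
  # g2: E in both -> E ; g3: NE in both -> NE
  mask <- rbind(c(TRUE, TRUE, TRUE, TRUE, FALSE),
                c(TRUE, TRUE, TRUE, TRUE, TRUE),
                c(FALSE, FALSE, FALSE, FALSE, FALSE))
  dimnames(mask) <- list(genes, cells)
  scr <- screenFromMask(mask, ctx)
  common <- labelCommon(scr)
  expect_identical(unname(geneLabels(common)[genes]), c("NE", "E", "NE"))
  # duplicating a cell-line column never changes the two-level mode
  mask2 <- cbind(mask, a1bis = mask[, "a1"])
  scr2 <- screenFromMask(mask2, setNames(c(ctx, "A"), colnames(mask2)))
  expect_identical(geneLabels(labelCommon(scr2))[genes],
                   geneLabels(common)[genes])
})

test_that("uncommon context-specific genes are the set difference", {
  mk <- function(labels, ctx) {
    new("LabelAssignment", labels = labels,
        partials = matrix(labels, length(labels), 1,
                          dimnames = list(names(labels), "u1")),
        classes = c("E", "NE"), context = ctx,
        thresholds = data.frame(), dropped = character())
  }
  cs <- mk(c(A = "E", B = "E", C = "NE"), "t1")
  common <- mk(c(A = "NE", B = "E", C = "NE"), "common")
  expect_identical(ucsGenes(cs, common), "A")
  expect_identical(ucsGenes(mk(c(B = "E"), "t1"), common), character(0))
  allNE <- mk(c(A = "NE", B = "NE"), "common")
  expect_identical(ucsGenes(cs, allNE), c("A", "B"))
})

test_that("screen filter enforces context size and missingness rules", {
  set.seed(7)
  genes <- paste0("g", 1:50)
  cells <- c(paste0("a", 1:10), paste0("b", 1:9))
  ctx <- setNames(c(rep("A", 10), rep("B", 9)), cells)
  m <- matrix(rnorm(length(genes) * length(cells)), length(genes),
              dimnames = list(genes, cells))
  # after B is dropped 10 cells remain: 96% missing impossible; use exact
  # counts instead: 10 cells -> >9.5 means 10 missing; 95% of 10 = 9.5
  m["g1", paste0("a", 1:10)] <- NA          # 100% missing in remaining
  m["g2", paste0("a", 1:9)] <- NA           # 90% -> kept
  scr <- ScoreScreen(m, ctx)
  expect_message(out <- filterScreen(scr, minCellLines = 10), "removed")
  expect_false("B" %in% contextNames(out))      # 9 cell lines: dropped
  expect_false("g1" %in% rownames(out))
  expect_true("g2" %in% rownames(out))
  # boundary: exactly 95% missing is retained, 96% is dropped
  m2 <- matrix(rnorm(100 * 25), 100, 25,
               dimnames = list(paste0("g", 1:100), paste0("c", 1:25)))
  m2["g1", 1:24] <- NA                      # 96% > 95% -> dropped
  m2["g2", 1:19] <- NA                      # 76% -> kept
  m2["g3", 1:23] <- NA                      # 92% -> kept
  scr2 <- ScoreScreen(m2, setNames(rep("A", 25), colnames(m2)))
  out2 <- suppressMessages(filterScreen(scr2, minCellLines = 10))
  expect_false("g1" %in% rownames(out2))
  expect_true(all(c("g2", "g3") %in% rownames(out2)))
  # exactly at the limit: 19/20 = 95% kept
  m4 <- matrix(rnorm(10 * 20), 10, 20,
               dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  m4["g1", 1:19] <- NA
  scr4 <- ScoreScreen(m4, setNames(rep("A", 20), colnames(m4)))
  expect_true("g1" %in%
                rownames(suppressMessages(filterScreen(scr4))))
  expect_error(suppressMessages(
    filterScreen(scr, minCellLines = 11)), "no context")
})

test_that("three-class refinement partitions the universe and keeps E", {
  syn <- suppressMessages(syntheticScores(
    nGenes = 400, contexts = c(a = 12), missingFrac = 0.02,
    aeLayer = list(fraction = 0.1, mean = -0.8, sd = 0.1), seed = 21))
  scr <- suppressMessages(filterScreen(syn$screen))
  two <- suppressMessages(labelContext(scr, "a"))
  three <- suppressMessages(labelThreeClass(scr, "a", two))
  l2 <- geneLabels(two)
  l3 <- geneLabels(three)
  expect_setequal(names(l3), names(l2))
  # E set identical between runs
  expect_identical(essentialGenes(three, "E"), essentialGenes(two, "E"))
  # aE u sNE = two-class NE, pairwise disjoint by construction
  expect_setequal(c(essentialGenes(three, "aE"),
                    essentialGenes(three, "sNE")),
                  essentialGenes(two, "NE"))
  expect_length(intersect(essentialGenes(three, "aE"),
                          essentialGenes(three, "sNE")), 0)
})

test_that("second pass threshold lands in the gap of a bimodal NE column", {
  # NE-restricted column bimodal at -0.8 and 0.0: the aE/sNE cut must agree
  # with the direct between-class-variance maximiser
  set.seed(31)
  neScores <- c(rnorm(40, -0.8, 0.05), rnorm(160, 0, 0.05))
  tHist <- otsuThreshold(neScores)
  tScan <- otsuScanOracle(neScores)
  expect_gt(tHist, -0.7)
  expect_lt(tHist, -0.1)
  expect_equal(sum(neScores < tHist), sum(neScores < tScan))
  # end to end: plant E at -3 plus that NE mixture in every cell line
  genes <- sprintf("g%03d", 1:220)
  cells <- paste0("c", 1:10)
  m <- vapply(cells, function(cc)
    c(rnorm(20, -3, 0.05), rnorm(40, -0.8, 0.05), rnorm(160, 0, 0.05)),
    numeric(220))
  rownames(m) <- genes
  scr <- ScoreScreen(m, setNames(rep("t", 10), cells))
  three <- suppressMessages(labelThreeClass(scr, "t"))
  lab <- geneLabels(three)
  expect_true(all(lab[genes[1:20]] == "E"))
  expect_true(mean(lab[genes[21:60]] == "aE") >= 0.95)
  expect_true(mean(lab[genes[61:220]] == "sNE") >= 0.95)
})

test_that("even splits at either level resolve to the not-essential class", {
  # 2 E + 2 NE partial labels -> NE; 1 aE + 1 sNE -> sNE
  genes <- c("g1", "g2")
  cells <- paste0("c", 1:4)
  mask <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                c(FALSE, FALSE, FALSE, FALSE))
  dimnames(mask) <- list(genes, cells)
  scr <- screenFromMask(mask, setNames(rep("t", 4), cells))
  expect_identical(unname(geneLabels(labelContext(scr, "t"))["g1"]), "NE")
  # aE/sNE tie via the internal mode helper on an even split
  expect_identical(crisprEssentials:::.modeLabel(c("aE", "sNE"), "sNE"),
                   "sNE")
  expect_identical(crisprEssentials:::.modeLabel(c("E", "NE"), "NE"), "NE")
  expect_identical(crisprEssentials:::.modeLabel(c("E", "E", "NE"), "NE"),
                   "E")
})
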