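triangle <- data.frame(node1 = c("a", "a", "b"),
                       node2 = c("b", "c", "c"),
                       weight = 1)

test_that("walks stay inside a closed component and honour the config", {
  cfg <- walkConfig(dimensions = 4, walkLength = 5, walksPerNode = 3,
                    seed = 2)
  walks <- generateWalks(triangle, cfg)
  expect_length(walks, 9L)                       # 3 nodes x 3 walks
  expect_true(all(unlist(walks) %in% c("a", "b", "c")))
  expect_true(all(lengths(walks) == 5L))
})

test_that("walks are deterministic given the seed", {
  cfg <- walkConfig(walkLength = 10, walksPerNode = 2, seed = 7)
  expect_identical(generateWalks(triangle, cfg),
                   generateWalks(triangle, cfg))
  cfg2 <- walkConfig(walkLength = 10, walksPerNode = 2, seed = 8)
  expect_false(identical(generateWalks(triangle, cfg),
                         generateWalks(triangle, cfg2)))
})

test_that("isolated nodes give length-1 walks and are absent from tables", {
  cfg <- walkConfig(dimensions = 4, walkLength = 5, walksPerNode = 2,
                    epochs = 1, seed = 1)
  expect_message(
    walks <- generateWalks(triangle, cfg, nodes = c("a", "b", "c", "zz")),
    "isolated")
  expect_true(any(lengths(walks) == 1L))
  expect_message(
    emb <- embedNodes(triangle, cfg, nodes = c("a", "b", "c", "zz")),
    "isolated")
  expect_false("zz" %in% rownames(emb))
  expect_setequal(rownames(emb), c("a", "b", "c"))
})

test_that("p=q=1 walk transitions follow the uniform first-order law", {
  # star-plus-path graph with distinct degrees
  edges <- data.frame(node1 = c("h", "h", "h", "x"),
                      node2 = c("x", "y", "z", "y"),
                      weight = 1)
  cfg <- walkConfig(walkLength = 200, walksPerNode = 40, seed = 3)
  walks <- generateWalks(edges, cfg)
  counts <- countTransitions(walks)
  oracle <- secondOrderOracle(edges, 1, 1)
  for (key in names(counts)) {
    n <- sum(counts[[key]])
    for (nb in names(counts[[key]])) {
      pHat <- counts[[key]][[nb]] / n
      p0 <- oracle[[key]][[nb]]
      se <- sqrt(p0 * (1 - p0) / n)
      expect_lt(abs(pHat - p0), 3 * se + 1e-9)
    }
  }
})

test_that("second-order bias matches the normalised weights on a path", {
  # 4-node path a-b-c-d, p = 0.25, q = 4
  path <- data.frame(node1 = c("a", "b", "c"), node2 = c("b", "c", "d"),
                     weight = 1)
  cfg <- walkConfig(walkLength = 400, walksPerNode = 80, p = 0.25, q = 4,
                    seed = 5)
  walks <- generateWalks(path, cfg)
  counts <- countTransitions(walks)
  oracle <- secondOrderOracle(path, 0.25, 4)
  # from state (a,b): return to a with bias 1/p = 4, advance to c with 1/q
  expect_equal(unname(oracle[["a->b"]]["a"]), 4 / 4.25)
  checked <- 0L
  for (key in names(counts)) {
    n <- sum(counts[[key]])
    if (n < 500) next
    for (nb in names(oracle[[key]])) {
      pHat <- if (is.na(counts[[key]][nb])) 0 else counts[[key]][[nb]] / n
      p0 <- oracle[[key]][[nb]]
      se <- sqrt(p0 * (1 - p0) / n)
      expect_lt(abs(pHat - p0), 3 * se + 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 4L)
})

test_that("embeddings have the configured dimension and are reproducible", {
  g <- syntheticGraph(nBlocks = 2, blockSize = 15, pIn = 0.4, pOut = 0.02,
                      seed = 4)
  cfg <- walkConfig(dimensions = 16, walkLength = 20, walksPerNode = 5,
                    epochs = 2, seed = 9)
  e1 <- embedNodes(g$edges, cfg)
  e2 <- embedNodes(g$edges, cfg)
  expect_identical(e1, e2)
  expect_equal(ncol(e1), 16L)
  expect_identical(colnames(e1)[1L], "n2v_0")
  expect_setequal(rownames(e1), unique(c(g$edges$node1, g$edges$node2)))
})

test_that("edge-list row order does not change the embedded node set", {
  g <- syntheticGraph(nBlocks = 2, blockSize = 10, pIn = 0.5, pOut = 0.05,
                      seed = 6)
  cfg <- walkConfig(dimensions = 8, walkLength = 10, walksPerNode = 3,
                    epochs = 1, seed = 2)
  shuf <- g$edges[sample(nrow(g$edges)), ]
  expect_setequal(rownames(embedNodes(g$edges, cfg)),
                  rownames(embedNodes(shuf, cfg)))
})

test_that("embedding separates planted communities", {
  g <- syntheticGraph(nBlocks = 2, blockSize = 20, pIn = 0.4, pOut = 0.02,
                      seed = 10)
  cfg <- walkConfig(dimensions = 32, walkLength = 30, walksPerNode = 8,
                    epochs = 3, seed = 11)
  emb <- embedNodes(g$edges, cfg)
  cs <- emb / sqrt(rowSums(emb^2))
  S <- cs %*% t(cs)
  blk <- g$blocks[rownames(emb)]
  same <- outer(blk, blk, "==") & upper.tri(S)
  diff <- outer(blk, blk, "!=") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})

test_that("degenerate graphs are rejected", {
  expect_error(generateWalks(triangle[0, ], walkConfig()), "no edges")
  expect_error(walkConfig(p = 0), "p > 0")
})
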