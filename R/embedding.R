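#' @useDynLib crisprEssentials, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Configuration for biased random-walk node embedding
#'
#' Defaults follow the original node2vec settings: 10 walks of length 80 per
#' node, window 10, return parameter \code{p} and in-out parameter \code{q}
#' both 1 (a first-order weighted walk), 5 training epochs, 128 dimensions.
#' Edge confidences are used as walk weights.
#'
#' @param dimensions embedding length per node.
#' @param walkLength steps per walk.
#' @param walksPerNode walks started from each node.
#' @param window skip-gram context window.
#' @param p return parameter (> 0); larger discourages returning to the
#'   previous node.
#' @param q in-out parameter (> 0); larger keeps the walk local (BFS-like).
#' @param epochs skip-gram training epochs.
#' @param negative negative samples per positive pair.
#' @param alpha initial learning rate.
#' @param seed RNG seed controlling walks, initialisation and sampling.
#' @return a validated list of class \code{WalkConfig}.
#' @export
walkConfig <- function(dimensions = 128L, walkLength = 80L,
                       walksPerNode = 10L, window = 10L, p = 1, q = 1,
                       epochs = 5L, negative = 5L, alpha = 0.025,
                       seed = 1L) {
  stopifnot(dimensions >= 1L, walkLength >= 1L, walksPerNode >= 1L,
            window >= 1L, p > 0, q > 0, epochs >= 1L, negative >= 1L)
  structure(list(dimensions = as.integer(dimensions),
                 walkLength = as.integer(walkLength),
                 walksPerNode = as.integer(walksPerNode),
                 window = as.integer(window), p = p, q = q,
                 epochs = as.integer(epochs),
                 negative = as.integer(negative), alpha = alpha,
                 seed = as.integer(seed)),
            class = "WalkConfig")
}

# Build sorted 0-based adjacency lists (+ aligned weights) from a canonical
# edge data.frame; nodes may add isolated vertices.
.adjacency <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("node1", "node2", "weight")], directed = FALSE,
    vertices = nodes)
  ids <- igraph::V(g)$name
  n <- length(ids)
  adj <- vector("list", n)
  wts <- vector("list", n)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  for (i in seq_len(n)) { adj[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1L]; b <- el[k, 2L]
    adj[[a]] <- c(adj[[a]], b - 1L); wts[[a]] <- c(wts[[a]], w[k])
    adj[[b]] <- c(adj[[b]], a - 1L); wts[[b]] <- c(wts[[b]], w[k])
  }
  for (i in seq_len(n)) {
    o <- order(adj[[i]])
    adj[[i]] <- adj[[i]][o]
    wts[[i]] <- wts[[i]][o]
  }
  list(ids = ids, adj = adj, wts = wts)
}

#' Generate biased second-order random walks
#'
#' From every non-isolated node, starts \code{walksPerNode} walks of
#' \code{walkLength} steps. Transition weight from the previous node
#' \code{t} through the current node to neighbour \code{x} with edge weight
#' \code{w} is \code{w/p} if \code{x == t}, \code{w} if \code{x} neighbours
#' \code{t}, and \code{w/q} otherwise. Deterministic given \code{cfg$seed}.
#'
#' @param edges canonical edge data.frame (see \code{\link{edgeList}}).
#' @param cfg a \code{\link{walkConfig}}.
#' @param nodes optional full vertex set; vertices without edges yield
#'   length-1 walks and are logged as isolated.
#' @return list of character vectors of node ids.
#' @export
generateWalks <- function(edges, cfg = walkConfig(), nodes = NULL) {
  if (nrow(edges) == 0L) stop("graph has no edges")
  a <- .adjacency(edges, nodes)
  iso <- vapply(a$adj, function(x) length(x) == 0L, logical(1L))
  if (any(iso))
    .logLine("generateWalks: ", sum(iso),
             " isolated node(s) yield length-1 walks: ",
             paste(a$ids[iso], collapse = ", "))
  walks <- .withSeed(cfg$seed,
    cpp_walks(a$adj, a$wts, cfg$p, cfg$q, cfg$walkLength,
              cfg$walksPerNode))
  lapply(walks, function(w) a$ids[w])
}

#' Embed graph nodes via walks + skip-gram
#'
#' Runs \code{\link{generateWalks}} and trains a skip-gram model with
#' negative sampling on the walk corpus. Isolated nodes are absent from the
#' result (and logged). Deterministic given \code{cfg$seed} (single worker).
#'
#' @inheritParams generateWalks
#' @return numeric matrix nodes x \code{cfg$dimensions}, rownames = node
#'   ids, colnames \code{n2v_0 ...}.
#' @export
embedNodes <- function(edges, cfg = walkConfig(), nodes = NULL) {
  if (nrow(edges) == 0L) stop("graph has no edges")
  a <- .adjacency(edges, nodes)
  iso <- vapply(a$adj, function(x) length(x) == 0L, logical(1L))
  emb <- .withSeed(cfg$seed, {
    walks <- cpp_walks(a$adj, a$wts, cfg$p, cfg$q, cfg$walkLength,
                       cfg$walksPerNode)
    walks <- walks[vapply(walks, length, 1L) > 1L]
    if (!length(walks)) stop("empty walk corpus")
    cpp_sgns(walks, length(a$ids), cfg$dimensions, cfg$window,
             cfg$epochs, cfg$negative, cfg$alpha)
  })
  rownames(emb) <- a$ids
  colnames(emb) <- paste0("n2v_", seq_len(cfg$dimensions) - 1L)
  if (any(iso)) {
    .logLine("embedNodes: excluded ", sum(iso), " isolated node(s): ",
             paste(a$ids[iso], collapse = ", "))
    emb <- emb[!iso, , drop = FALSE]
  }
  emb
}

#' Write / read an embedding table as CSV
#' @param embedding matrix from \code{\link{embedNodes}}.
#' @param path CSV path; first column \code{node}.
#' @export
writeEmbedding <- function(embedding, path) {
  df <- data.frame(node = rownames(embedding), embedding,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
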