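#' Random-walk configuration
#'
#' Hyperparameters for DeepWalk/node2vec-style walk generation and the
#' co-occurrence factorization.  Defaults follow common DeepWalk practice:
#' 10 walks of length 40 per node, window 5, 64 dimensions, and uniform
#' node2vec bias (`p = q = 1`, i.e. plain weighted random walks).
#'
#' @param walks_per_node number of walks started at every node.
#' @param walk_length maximum walk length (nodes per walk).
#' @param p node2vec return parameter (probability of revisiting the
#'   previous node is proportional to `weight / p`).
#' @param q node2vec in-out parameter (moving away from the previous node's
#'   neighbourhood is proportional to `weight / q`).
#' @param window co-occurrence window for the factorization.
#' @param dim embedding dimensionality (reduced with a warning if the
#'   co-occurrence matrix has lower rank).
#' @param seed integer seed; every source of walk randomness derives from it.
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(walks_per_node = 10, walk_length = 40,
                        p = 1, q = 1, window = 5, dim = 64, seed = 1) {
  stopifnot(walks_per_node >= 1, walk_length >= 1, p > 0, q > 0,
            window >= 1, dim >= 1)
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 p = p, q = q, window = as.integer(window),
                 dim = as.integer(dim), seed = as.integer(seed)),
            class = "walk_config")
}

#' Generate a random-walk corpus over a PPI graph
#'
#' Starts `walks_per_node` walks at every node (in canonical sorted order).
#' Transition probabilities are proportional to edge weights, modulated by
#' the node2vec `p`/`q` bias when these differ from 1.  Isolated nodes yield
#' length-1 walks.  The walk RNG is seeded per start node from
#' `(seed, rank of the node in canonical sorted order)`, so the corpus is
#' independent of node insertion order, byte-identical across runs with the
#' same seed, and equivariant under order-preserving renamings.
#'
#' @param graph a [ppi_graph()].
#' @param config a [walk_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return List of character vectors (one per walk), ordered by start node.
#' @export
generate_walks <- function(graph, config = walk_config(), seed = config$seed) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (!length(graph$nodes)) {
    warning("empty graph: empty walk corpus")
    return(list())
  }
  adj <- adjacency_list(graph)
  walks <- vector("list", length(graph$nodes) * config$walks_per_node)
  idx <- 1L
  for (rank in seq_along(graph$nodes)) {  # graph$nodes is sorted
    node <- graph$nodes[rank]
    set.seed(derive_seed(seed, sprintf("node-%d", rank)))
    for (w in seq_len(config$walks_per_node)) {
      walks[[idx]] <- one_walk(node, adj, config)
      idx <- idx + 1L
    }
  }
  walks
}

# adjacency list: per node, a list(nbr = character, w = numeric)
adjacency_list <- function(graph) {
  adj <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (node in graph$nodes) adj[[node]] <- list(nbr = character(), w = numeric())
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    a <- e$from[i]; b <- e$to[i]; w <- e$weight[i]
    adj[[a]]$nbr <- c(adj[[a]]$nbr, b); adj[[a]]$w <- c(adj[[a]]$w, w)
    adj[[b]]$nbr <- c(adj[[b]]$nbr, a); adj[[b]]$w <- c(adj[[b]]$w, w)
  }
  adj
}

one_walk <- function(start, adj, config) {
  walk <- character(config$walk_length)
  walk[1] <- start
  prev <- NA_character_
  cur <- start
  len <- 1L
  while (len < config$walk_length) {
    nb <- adj[[cur]]
    if (!length(nb$nbr)) break
    probs <- nb$w
    if (!is.na(prev) && (config$p != 1 || config$q != 1)) {
      prev_nbrs <- adj[[prev]]$nbr
      bias <- ifelse(nb$nbr == prev, 1 / config$p,
                     ifelse(nb$nbr %in% prev_nbrs, 1, 1 / config$q))
      probs <- probs * bias
    }
    nxt <- if (length(nb$nbr) == 1L) nb$nbr else
      sample(nb$nbr, 1L, prob = probs)
    len <- len + 1L
    walk[len] <- nxt
    prev <- cur
    cur <- nxt
  }
  walk[seq_len(len)]
}

#' Factorize a walk corpus into node vectors (PPMI + truncated SVD)
#'
#' Builds the symmetric window-based co-occurrence matrix over the corpus,
#' transforms it to positive pointwise mutual information (PPMI) and
#' factorizes by truncated SVD to `config$dim` dimensions.  Node vectors are
#' `U_d * sqrt(S_d)`.  The result is deterministic given the corpus; sign
#' ambiguity is resolved by making the largest-magnitude entry of each
#' singular vector positive.  If the matrix rank is below `dim`, the
#' dimensionality is reduced with a warning.
#'
#' @param corpus list of character vectors, e.g. from [generate_walks()].
#' @param config a [walk_config()]; `window` and `dim` are used.
#' @return An object of class `node_embedding`: list with `nodes`, `vectors`
#'   (matrix, one row per node), `walk_dim`, `anno_dim` and `alpha`.
#' @export
embed_from_walks <- function(corpus, config = walk_config()) {
  if (!length(corpus)) stop("empty walk corpus")
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  nv <- length(vocab)

  ii <- integer(0); jj <- integer(0)
  for (walk in corpus) {
    ids <- match(walk, vocab)
    L <- length(ids)
    if (L < 2) next
    for (k in seq_len(min(config$window, L - 1L))) {
      a <- ids[seq_len(L - k)]
      b <- ids[seq(k + 1L, L)]
      ii <- c(ii, a, b)
      jj <- c(jj, b, a)
    }
  }
  if (!length(ii)) {
    # corpus of isolated nodes only: zero embedding at reduced dim 1
    warning("no co-occurrences in corpus; returning zero vectors")
    vecs <- matrix(0, nv, 1, dimnames = list(vocab, NULL))
    return(new_node_embedding(vocab, vecs))
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nv, nv))
  X <- as.matrix(X)

  total <- sum(X)
  r <- rowSums(X); cc <- colSums(X)
  P <- X * total / outer(pmax(r, 1e-300), pmax(cc, 1e-300))
  M <- matrix(0, nv, nv)
  pos <- X > 0
  M[pos] <- pmax(0, log(P[pos]))

  sv <- svd(M)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  d <- min(config$dim, max(rank, 1L))
  if (d < config$dim) {
    warning("co-occurrence rank ", rank, " below requested dim ",
            config$dim, "; reduced to ", d)
  }
  U <- sv$u[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(d)) {
    m <- which.max(abs(U[, j]))
    if (U[m, j] < 0) U[, j] <- -U[, j]
  }
  vecs <- U %*% diag(sqrt(sv$d[seq_len(d)]), d)
  rownames(vecs) <- vocab
  new_node_embedding(vocab, vecs)
}

new_node_embedding <- function(nodes, vectors, anno_dim = 0L, alpha = 0) {
  structure(list(nodes = nodes, vectors = vectors,
                 walk_dim = ncol(vectors) - anno_dim,
                 anno_dim = anno_dim, alpha = alpha),
            class = "node_embedding")
}

#' @export
print.node_embedding <- function(x, ...) {
  cat("node_embedding:", length(x$nodes), "nodes, walk dim", x$walk_dim)
  if (x$anno_dim > 0) {
    cat(", annotation dim", x$anno_dim, sprintf("(alpha = %g)", x$alpha))
  }
  cat("\n")
  invisible(x)
}

#' Embed a graph in one call
#'
#' Convenience wrapper: [generate_walks()] then [embed_from_walks()], with an
#' optional annotation block appended ([append_annotation_block()]).
#'
#' @param graph a [ppi_graph()].
#' @param config a [walk_config()].
#' @param seed integer seed, defaults to `config$seed`.
#' @param alpha if non-`NULL`, append the annotation-membership block with
#'   this weight.
#' @return A `node_embedding`.
#' @export
embed_graph <- function(graph, config = walk_config(), seed = config$seed,
                        alpha = NULL) {
  emb <- embed_from_walks(generate_walks(graph, config, seed), config)
  if (!is.null(alpha)) emb <- append_annotation_block(emb, graph, alpha)
  emb
}

#' Append an annotation-membership block to an embedding
#'
#' Each node receives a binary membership vector over the union of all term
#' identifiers in the graph (fixed sorted term order), L2-normalized and
#' scaled by `alpha`, concatenated to its walk-derived vector.  Nodes without
#' annotations get a zero block, so with `alpha = 0` (or no annotations)
#' downstream cosine similarities equal the walk-only similarities.
#'
#' @param embedding a `node_embedding` covering all graph nodes.
#' @param graph a [ppi_graph()] carrying the annotation sets.
#' @param alpha non-negative block weight (default 1).
#' @return A `node_embedding` with the extra columns.
#' @export
append_annotation_block <- function(embedding, graph, alpha = 1) {
  stopifnot(inherits(embedding, "node_embedding"),
            inherits(graph, "ppi_graph"), alpha >= 0)
  missing_nodes <- setdiff(graph$nodes, embedding$nodes)
  if (length(missing_nodes)) {
    stop("embedding lacks graph node(s): ",
         paste(utils::head(missing_nodes, 5), collapse = ", "))
  }
  terms <- sort(unique(unlist(graph$annotations, use.names = FALSE)))
  if (!length(terms)) return(embedding)
  block <- matrix(0, length(embedding$nodes), length(terms),
                  dimnames = list(embedding$nodes, terms))
  for (node in names(graph$annotations)) {
    hit <- graph$annotations[[node]]
    if (length(hit)) block[node, hit] <- 1
  }
  norms <- sqrt(rowSums(block^2))
  nz <- norms > 0
  block[nz, ] <- block[nz, , drop = FALSE] / norms[nz] * alpha
  vecs <- cbind(embedding$vectors[, seq_len(embedding$walk_dim), drop = FALSE],
                block)
  new_node_embedding(embedding$nodes, vecs,
                     anno_dim = length(terms), alpha = alpha)
}

#' Nearest neighbours in latent space
#'
#' Top-`k` other nodes by cosine similarity to `node`, descending; ties are
#' broken lexicographically by node id.
#'
#' @param embedding a `node_embedding`.
#' @param node a node id present in the embedding.
#' @param k non-negative number of neighbours.
#' @return data.frame with columns `node`, `similarity`.
#' @export
nearest_neighbours <- function(embedding, node, k) {
  stopifnot(inherits(embedding, "node_embedding"), k >= 0)
  if (!node %in% embedding$nodes) stop("unknown node: ", node)
  if (k == 0) return(data.frame(node = character(), similarity = numeric()))
  sims <- cosine_to_all(embedding$vectors, node)
  sims <- sims[names(sims) != node]
  ord <- order(-sims, names(sims))
  top <- utils::head(ord, k)
  data.frame(node = names(sims)[top], similarity = unname(sims[top]))
}

#' Export an embedding as text
#'
#' @param embedding a `node_embedding`.
#' @param path output file path.
#' @param format `"tsv"` (header `node`, `v1`..`vd`) or `"word2vec"`
#'   (count/dim header line, then space-separated rows).
#' @export
write_embedding <- function(embedding, path, format = c("tsv", "word2vec")) {
  format <- match.arg(format)
  v <- embedding$vectors
  if (format == "tsv") {
    df <- data.frame(node = rownames(v), v, check.names = FALSE)
    colnames(df) <- c("node", paste0("v", seq_len(ncol(v))))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(nrow(v), ncol(v)), con)
    writeLines(paste(rownames(v),
                     apply(v, 1, function(r) paste(format(r, digits = 8),
                                                   collapse = " "))), con)
  }
  invisible(path)
}
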