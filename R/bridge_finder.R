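#' Bridge query
#'
#' Parameters for intermediary-protein discovery between a target protein
#' and a set of query proteins (typically differentially abundant proteins).
#'
#' @param target node id of the protein of interest.
#' @param queries non-empty character vector of query node ids; must not
#'   contain `target`.
#' @param k neighbours per node used for latent-space candidate discovery
#'   and mutual-kNN linkage (default 10).
#' @param min_linked minimum number of distinct query proteins an
#'   intermediary must connect (default 4, i.e. strictly more than three).
#' @param max_path_len graph-distance cap for path-based candidates
#'   (default 3).
#' @param use_adjacency count a direct graph edge to a query as a link
#'   (default TRUE).
#' @param use_mutual_knn count mutual k-nearest-neighbourhood in latent
#'   space as a link (default TRUE).
#' @return A list of class `bridge_query`.
#' @export
bridge_query <- function(target, queries, k = 10, min_linked = 4,
                         max_path_len = 3, use_adjacency = TRUE,
                         use_mutual_knn = TRUE) {
  queries <- unique(as.character(queries))
  if (!length(queries)) stop("query set must be non-empty")
  if (target %in% queries) stop("target must not be among the queries")
  stopifnot(k >= 0, min_linked >= 1, max_path_len >= 1)
  structure(list(target = as.character(target), queries = queries,
                 k = as.integer(k), min_linked = as.integer(min_linked),
                 max_path_len = as.integer(max_path_len),
                 use_adjacency = isTRUE(use_adjacency),
                 use_mutual_knn = isTRUE(use_mutual_knn)),
            class = "bridge_query")
}

#' Find intermediary proteins bridging a target to query proteins
#'
#' Candidates are nodes (excluding the target and the queries) that either
#' appear among the `k` latent-space nearest neighbours of the target or of
#' any query, or lie on a shortest graph path of length at most
#' `max_path_len` between the target and a query.  A candidate is *linked*
#' to a query if it is a direct graph neighbour of it, or if the two are
#' mutually within each other's `k` nearest neighbours in latent space
#' (each notion can be switched off in the [bridge_query()]).  Candidates
#' linked to at least `min_linked` distinct queries are reported, ranked by
#' linked-query count (desc), mean cosine similarity to the queries (desc),
#' then node id.
#'
#' @param graph a [ppi_graph()].
#' @param embedding a `node_embedding` covering the graph.
#' @param query a [bridge_query()].
#' @return An object of class `bridge_report`: list with `intermediaries`
#'   (data.frame: `node`, `linked_query_count`, `mean_cosine_queries`,
#'   `cosine_target`, `rank`), `central` (filled by [central_protein()]),
#'   `enrichment` (filled by [enrich_terms()] if annotations are present) and
#'   `explanation_edges` (induced edge list on target, queries and
#'   intermediaries).
#' @export
find_intermediaries <- function(graph, embedding, query) {
  stopifnot(inherits(graph, "ppi_graph"),
            inherits(embedding, "node_embedding"),
            inherits(query, "bridge_query"))
  focus <- c(query$target, query$queries)
  absent <- setdiff(focus, graph$nodes)
  if (length(absent)) stop("node(s) absent from graph: ",
                           paste(absent, collapse = ", "))
  absent <- setdiff(focus, embedding$nodes)
  if (length(absent)) stop("node(s) absent from embedding: ",
                           paste(absent, collapse = ", "))

  knn <- lapply(stats::setNames(focus, focus), function(n)
    nearest_neighbours(embedding, n, query$k)$node)

  # latent-space candidates: anyone in a focus node's kNN list
  cand <- unique(unlist(knn, use.names = FALSE))

  # path candidates: nodes on shortest target-query paths of length <= cap
  ig <- as_igraph(graph)
  dist_tq <- igraph::distances(ig, v = query$target, to = query$queries,
                               weights = NA)
  reachable <- query$queries[is.finite(dist_tq[1, ]) &
                             dist_tq[1, ] <= query$max_path_len]
  if (length(reachable)) {
    sp <- igraph::all_shortest_paths(ig, from = query$target, to = reachable,
                                     weights = NA)$vpaths
    cand <- unique(c(cand, unlist(lapply(sp, function(v) v$name))))
  }
  cand <- sort(setdiff(cand, focus))

  # adjacency of candidates to queries
  adj_sets <- lapply(stats::setNames(query$queries, query$queries), function(qn) {
    e <- graph$edges
    c(e$to[e$from == qn], e$from[e$to == qn])
  })
  # kNN sets of every candidate (for the mutual-kNN linkage)
  cand_knn <- lapply(stats::setNames(cand, cand), function(n)
    nearest_neighbours(embedding, n, query$k)$node)

  linked_count <- vapply(cand, function(n) {
    linked <- vapply(query$queries, function(qn) {
      by_edge <- query$use_adjacency && n %in% adj_sets[[qn]]
      by_knn <- query$use_mutual_knn &&
        (n %in% knn[[qn]]) && (qn %in% cand_knn[[n]])
      by_edge || by_knn
    }, logical(1))
    sum(linked)
  }, integer(1))

  keep <- cand[linked_count >= query$min_linked]
  mean_cos <- vapply(keep, function(n) {
    sims <- cosine_to_all(embedding$vectors, n)
    mean(sims[query$queries])
  }, numeric(1))
  cos_target <- vapply(keep, function(n) {
    cosine_to_all(embedding$vectors, query$target)[n]
  }, numeric(1))

  ord <- order(-linked_count[keep], -mean_cos, keep)
  inter <- data.frame(node = keep[ord],
                      linked_query_count = unname(linked_count[keep][ord]),
                      mean_cosine_queries = unname(mean_cos[ord]),
                      cosine_target = unname(cos_target[ord]),
                      rank = seq_along(ord))
  rownames(inter) <- NULL

  expl_nodes <- c(query$target, query$queries, inter$node)
  e <- graph$edges
  expl <- e[e$from %in% expl_nodes & e$to %in% expl_nodes, , drop = FALSE]
  rownames(expl) <- NULL

  report <- structure(list(intermediaries = inter, central = NA_character_,
                           enrichment = NULL, explanation_edges = expl,
                           query = query),
                      class = "bridge_report")
  report$central <- central_protein(report, embedding, query)
  if (length(graph$annotations) && nrow(inter)) {
    report$enrichment <- enrich_terms(inter$node, graph,
                                      background = graph$nodes)
  }
  report
}

#' @export
print.bridge_report <- function(x, ...) {
  cat("bridge_report:", nrow(x$intermediaries), "intermediary node(s);",
      "central protein:", x$central, "\n")
  if (nrow(x$intermediaries)) print(utils::head(x$intermediaries, 10))
  invisible(x)
}

#' Central protein of a bridge report
#'
#' Among the target, the reported intermediaries and the queries, returns
#' the node minimizing the mean cosine *distance* (1 - similarity) to all
#' query nodes; ties are broken lexicographically by node id.
#'
#' @param report a `bridge_report` from [find_intermediaries()].
#' @param embedding the `node_embedding` used for the report.
#' @param query the [bridge_query()] used for the report.
#' @return A node id.
#' @export
central_protein <- function(report, embedding, query) {
  stopifnot(inherits(report, "bridge_report"))
  pool <- sort(unique(c(query$target, report$intermediaries$node,
                        query$queries)))
  score <- vapply(pool, function(n) {
    sims <- cosine_to_all(embedding$vectors, n)
    mean(1 - sims[query$queries])
  }, numeric(1))
  pool[order(score, pool)][1]
}

#' Hypergeometric term enrichment with BH-FDR
#'
#' For every annotation term hit by at least one member, computes the
#' one-sided hypergeometric upper-tail p-value (probability of an overlap at
#' least as large as observed, drawing `|members|` nodes from the annotated
#' background) and Benjamini-Hochberg q-values across the tested terms.
#' Terms never annotated in the background are skipped.
#'
#' @param members non-empty character vector of nodes, a subset of
#'   `background`.
#' @param graph a [ppi_graph()] whose `annotations` provide the node-to-term
#'   map.
#' @param background character vector of background nodes (default: all
#'   graph nodes).
#' @return data.frame with columns `term`, `overlap`, `term_size`,
#'   `p_value`, `q_value`, sorted by `q_value`, `p_value`, `term`.
#' @export
enrich_terms <- function(members, graph, background = graph$nodes) {
  stopifnot(inherits(graph, "ppi_graph"))
  members <- unique(as.character(members))
  if (!length(members)) stop("members must be non-empty")
  if (!all(members %in% background)) {
    stop("members must be a subset of the background")
  }
  ann <- graph$annotations[intersect(names(graph$annotations), background)]
  if (!length(ann)) {
    return(data.frame(term = character(), overlap = integer(),
                      term_size = integer(), p_value = numeric(),
                      q_value = numeric()))
  }
  node_of <- rep(names(ann), lengths(ann))
  term_of <- unlist(ann, use.names = FALSE)
  terms_hit <- sort(unique(term_of[node_of %in% members]))
  if (!length(terms_hit)) {
    return(data.frame(term = character(), overlap = integer(),
                      term_size = integer(), p_value = numeric(),
                      q_value = numeric()))
  }
  N <- length(unique(background))
  n <- length(members)
  res <- lapply(terms_hit, function(tm) {
    carriers <- unique(node_of[term_of == tm])
    K <- length(carriers)
    k <- length(intersect(carriers, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, p_value = p)
  })
  res <- do.call(rbind, res)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$q_value, res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a bridge report to a directory
#'
#' Emits `intermediaries.tsv`, `enrichment.tsv` (when present),
#' `explanation_edges.tsv`, `explanation.graphml` and a `run_info.txt`
#' with the query parameters.
#'
#' @param report a `bridge_report`.
#' @param graph the [ppi_graph()] analysed.
#' @param dir output directory (created if needed).
#' @export
write_bridge_report <- function(report, graph, dir) {
  stopifnot(inherits(report, "bridge_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$intermediaries,
                     file.path(dir, "intermediaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$enrichment)) {
    utils::write.table(report$enrichment, file.path(dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$explanation_edges,
                     file.path(dir, "explanation_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expl_nodes <- unique(c(report$query$target, report$query$queries,
                         report$intermediaries$node))
  expl_nodes <- intersect(graph$nodes, expl_nodes)
  sub <- neighborhood_subgraph(graph, expl_nodes, 0)
  write_ppi_graphml(sub, file.path(dir, "explanation.graphml"))
  q <- report$query
  writeLines(c(paste("target:", q$target),
               paste("queries:", paste(q$queries, collapse = ",")),
               paste("k:", q$k),
               paste("min_linked:", q$min_linked),
               paste("max_path_len:", q$max_path_len),
               paste("use_adjacency:", q$use_adjacency),
               paste("use_mutual_knn:", q$use_mutual_knn),
               paste("central:", report$central)),
             file.path(dir, "run_info.txt"))
  invisible(dir)
}
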