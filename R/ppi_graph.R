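#' Protein-protein interaction graphs
#'
#' A `ppi_graph` is an undirected, weighted protein graph with an optional
#' per-node set of annotation terms (GO-style identifiers).  Edge weights are
#' interaction confidences on the \[0, 1\] scale (STRING combined scores are
#' divided by 1000 on import).  Node identifiers are opaque, case-sensitive
#' tokens.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.  Self-loops
#'   are dropped (with a message), reciprocal duplicates merged keeping the
#'   maximum weight.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the nodes appearing in `edges`.  Extra names create isolated nodes.
#' @param annotations named list mapping node id to a character vector of
#'   term ids.  Names must be a subset of `nodes`.
#' @param score_threshold minimum confidence retained, inclusive.
#' @return An object of class `ppi_graph` with elements `nodes` (sorted
#'   character vector), `edges` (data.frame `from`, `to`, `weight` with
#'   `from < to`, sorted), `annotations` (named list of character vectors)
#'   and `score_threshold`.
#' @export
ppi_graph <- function(edges = NULL, nodes = NULL, annotations = list(),
                      score_threshold = 0) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0) ||
      any(edges$weight > 1)) {
    stop("edge weights must be finite and within [0, 1]")
  }

  loops <- edges$from == edges$to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }

  if (!nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
    all_nodes <- sort(unique(nodes))
    if (length(annotations)) {
      bad <- setdiff(names(annotations), all_nodes)
      if (length(bad)) {
        stop("annotation keys absent from graph: ",
             paste(bad, collapse = ", "))
      }
    }
    return(structure(list(nodes = all_nodes, edges = edges,
                          annotations = annotations,
                          score_threshold = score_threshold),
                     class = "ppi_graph"))
  }

  # canonical unordered pairs, duplicates merged by max weight
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  uk <- names(w)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                      to = vapply(parts, `[`, "", 2L),
                      weight = as.numeric(w),
                      stringsAsFactors = FALSE)

  edges <- edges[edges$weight >= score_threshold, , drop = FALSE]
  all_nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  if (length(annotations)) {
    bad <- setdiff(names(annotations), all_nodes)
    if (length(bad)) {
      stop("annotation keys absent from graph: ", paste(bad, collapse = ", "))
    }
    annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  }

  structure(list(nodes = all_nodes, edges = edges,
                 annotations = annotations,
                 score_threshold = score_threshold),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("ppi_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(score >= %g)", x$score_threshold), "\n")
  n_ann <- sum(lengths(x$annotations) > 0)
  if (n_ann) cat("  annotated nodes:", n_ann, "\n")
  invisible(x)
}

#' @export
format.ppi_graph <- function(x, ...) {
  sprintf("<ppi_graph: %d nodes, %d edges>", length(x$nodes), nrow(x$edges))
}

# igraph view of a ppi_graph (weights carried as 'weight' attribute)
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Load a STRING-format protein-links edge list
#'
#' Reads a space- or tab-delimited file with at least three columns
#' (protein a, protein b, combined score).  A header line such as
#' `protein1 protein2 combined_score` is detected and skipped.  The score
#' scale is auto-detected: any value greater than 1 implies the STRING 0-1000
#' integer scale and the whole file is divided by 1000.  Edges below
#' `score_threshold` (after normalization) are removed; the comparison is
#' inclusive, so `score_threshold = 0.7` keeps a score of exactly 0.7.
#'
#' @param path file path.
#' @param score_threshold minimum normalized confidence kept (default 0.7,
#'   the customary STRING "high confidence" cut).
#' @param dialect `"auto"` (any whitespace), `"tab"` or `"space"`.
#' @param score_scale `"auto"` (default), `"1000"` to force division by 1000,
#'   or `"unit"` to take scores as already in \[0, 1\].
#' @param strip_species_prefix drop a leading `9606.`-style NCBI taxon prefix
#'   from identifiers (default FALSE).
#' @return A [ppi_graph()].
#' @export
load_string_edges <- function(path, score_threshold = 0.7,
                              dialect = c("auto", "tab", "space"),
                              score_scale = c("auto", "1000", "unit"),
                              strip_species_prefix = FALSE) {
  dialect <- match.arg(dialect)
  score_scale <- match.arg(score_scale)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty edge file: ", path)
    return(ppi_graph(score_threshold = score_threshold))
  }

  sep <- switch(dialect, auto = "[ \t]+", tab = "\t", space = " +")
  fields <- strsplit(trimws(lines), sep)

  first_line <- 1L
  f1 <- fields[[1]]
  if (length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3])))) {
    first_line <- 2L  # header
  }
  if (first_line > length(fields)) {
    warning("edge file contains only a header: ", path)
    return(ppi_graph(score_threshold = score_threshold))
  }

  n <- length(fields)
  from <- to <- character(n - first_line + 1L)
  score <- numeric(n - first_line + 1L)
  for (i in seq(first_line, n)) {
    f <- fields[[i]]
    j <- i - first_line + 1L
    if (length(f) < 3) stop("malformed line ", i, " in ", path,
                            ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s)) stop("malformed line ", i, " in ", path,
                       ": non-numeric score '", f[3], "'")
    from[j] <- f[1]; to[j] <- f[2]; score[j] <- s
  }

  if (strip_species_prefix) {
    from <- sub("^[0-9]+\\.", "", from)
    to <- sub("^[0-9]+\\.", "", to)
  }
  divide <- switch(score_scale,
                   auto = any(score > 1),
                   "1000" = TRUE,
                   unit = FALSE)
  if (divide) score <- score / 1000

  ppi_graph(data.frame(from = from, to = to, weight = score),
            score_threshold = score_threshold)
}

#' Attach node annotations from a two-column TSV
#'
#' Merges `node_id<TAB>term_id` pairs into the graph's annotation sets.
#' Pairs referencing nodes absent from the graph are not added; they are
#' returned in the `skipped_annotations` attribute of the result.  Duplicate
#' pairs are idempotent (term sets).
#'
#' @param graph a [ppi_graph()].
#' @param annotations file path to a two-column TSV, or a data.frame with
#'   columns `node_id`, `term_id`.
#' @return The graph with merged annotations; `attr(, "skipped_annotations")`
#'   holds the skipped pairs as a data.frame.
#' @export
attach_annotations <- function(graph, annotations) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (is.character(annotations)) {
    annotations <- utils::read.table(annotations, sep = "\t", header = FALSE,
                                     col.names = c("node_id", "term_id"),
                                     colClasses = "character", quote = "")
  }
  stopifnot(all(c("node_id", "term_id") %in% names(annotations)))
  ann <- annotations[, c("node_id", "term_id")]
  known <- ann$node_id %in% graph$nodes
  skipped <- ann[!known, , drop = FALSE]
  if (nrow(skipped)) {
    message(nrow(skipped), " annotation pair(s) referencing unknown nodes skipped")
  }
  ann <- ann[known, , drop = FALSE]
  merged <- graph$annotations
  for (node in unique(ann$node_id)) {
    terms <- ann$term_id[ann$node_id == node]
    merged[[node]] <- sort(unique(c(merged[[node]], terms)))
  }
  out <- graph
  out$annotations <- merged
  attr(out, "skipped_annotations") <- skipped
  out
}

#' Induced subgraph around seed nodes
#'
#' Returns the induced subgraph on all nodes within graph distance
#' `radius` (unweighted hops) of any seed, with annotations restricted to
#' the retained nodes.
#'
#' @param graph a [ppi_graph()].
#' @param seeds character vector of node ids present in the graph.
#' @param radius non-negative integer.
#' @return A [ppi_graph()].
#' @export
neighborhood_subgraph <- function(graph, seeds, radius) {
  stopifnot(inherits(graph, "ppi_graph"), radius >= 0)
  unknown <- setdiff(seeds, graph$nodes)
  if (length(unknown)) {
    stop("unknown seed node(s): ", paste(unknown, collapse = ", "))
  }
  ig <- as_igraph(graph)
  hoods <- igraph::ego(ig, order = radius, nodes = seeds, mode = "all")
  keep <- sort(unique(unlist(lapply(hoods, function(v) v$name))))
  sub <- igraph::induced_subgraph(ig, vids = keep)
  e <- igraph::as_data_frame(sub, what = "edges")
  ann <- graph$annotations[intersect(names(graph$annotations), keep)]
  ppi_graph(data.frame(from = e$from, to = e$to, weight = e$weight),
            nodes = keep, annotations = ann,
            score_threshold = graph$score_threshold)
}

#' Write a canonical edge-list TSV
#'
#' Columns `node_a`, `node_b`, `score` with `node_a < node_b`, sorted
#' lexicographically; full numeric precision so that reloading with
#' [load_string_edges()] round-trips the graph.
#'
#' @param graph a [ppi_graph()].
#' @param path output file path.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "ppi_graph"))
  df <- data.frame(node_a = graph$edges$from, node_b = graph$edges$to,
                   score = format(graph$edges$weight, digits = 17,
                                  scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a graph as GraphML
#'
#' @param graph a [ppi_graph()].
#' @param path output file path.
#' @export
write_ppi_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "ppi_graph"))
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
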