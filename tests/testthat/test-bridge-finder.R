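# deterministic toy: target FAM-like node, 6 query nodes, X wired to the
# target and 5 queries, Y wired to 2 queries only
toy_bridge_graph <- function() {
  queries <- sprintf("Q%d", 1:6)
  e <- rbind(data.frame(from = "X", to = c("TGT", queries[1:5])),
             data.frame(from = "Y", to = queries[1:2]),
             data.frame(from = "TGT", to = "Q6"),
             data.frame(from = "Q6", to = "Y"))
  e$weight <- 0.9
  list(graph = ppi_graph(e), target = "TGT", queries = queries)
}

test_that("the more-than-three-queries rule includes X and excludes Y", {
  toy <- toy_bridge_graph()
  emb <- suppressWarnings(embed_graph(toy$graph, walk_config(seed = 1)))
  q <- bridge_query(toy$target, toy$queries, use_mutual_knn = FALSE)
  rep <- find_intermediaries(toy$graph, emb, q)
  expect_true("X" %in% rep$intermediaries$node)
  expect_false("Y" %in% rep$intermediaries$node)
  expect_true(all(rep$intermediaries$linked_query_count >= 4))
})

test_that("exactly 3 linked queries is excluded, 4 is included", {
  queries <- sprintf("Q%d", 1:6)
  make_node <- function(nm, k) data.frame(from = nm, to = c("TGT", queries[seq_len(k)]))
  e <- rbind(make_node("THREE", 3), make_node("FOUR", 4))
  e$weight <- 0.9
  # connect remaining queries so they exist in the graph
  e <- rbind(e, data.frame(from = "TGT", to = queries, weight = 0.9))
  g <- ppi_graph(e)
  emb <- suppressWarnings(embed_graph(g, walk_config(seed = 1)))
  q <- bridge_query("TGT", queries, use_mutual_knn = FALSE)
  rep <- find_intermediaries(g, emb, q)
  expect_true("FOUR" %in% rep$intermediaries$node)
  expect_false("THREE" %in% rep$intermediaries$node)
})

test_that("raising min_linked never adds intermediaries", {
  pg <- make_planted_bridge_graph(planted_graph_spec(seed = 4))
  emb <- suppressWarnings(embed_graph(pg$graph, walk_config(seed = 4)))
  prev <- NULL
  for (ml in c(2, 4, 6, 9)) {
    rep <- find_intermediaries(pg$graph, emb,
                               bridge_query(pg$target, pg$queries,
                                            min_linked = ml))
    cur <- rep$intermediaries$node
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("query validation rejects empty and self-including query sets", {
  expect_error(bridge_query("T", character()), "non-empty")
  expect_error(bridge_query("T", c("T", "Q")), "must not be among")
  toy <- toy_bridge_graph()
  emb <- suppressWarnings(embed_graph(toy$graph, walk_config(seed = 1)))
  expect_error(find_intermediaries(toy$graph, emb,
                                   bridge_query("TGT", "MISSING")),
               "absent")
})

test_that("planted bridges are recovered exactly at the default spec", {
  pg <- make_planted_bridge_graph(planted_graph_spec(seed = 1))
  emb <- suppressWarnings(embed_graph(pg$graph, walk_config(seed = 1)))
  rep <- find_intermediaries(pg$graph, emb,
                             bridge_query(pg$target, pg$queries))
  expect_setequal(rep$intermediaries$node, pg$bridges)
})

test_that("central protein equals the brute-force mean-distance argmin", {
  set.seed(8)
  nodes <- sprintf("P%02d", 1:10)
  v <- matrix(rnorm(10 * 5), 10, dimnames = list(nodes, NULL))
  emb <- manual_embedding(v)
  queries <- nodes[2:5]
  g <- ppi_graph(data.frame(from = nodes[1], to = nodes[-1], weight = 0.9))
  rep <- find_intermediaries(g, emb,
                             bridge_query(nodes[1], queries, k = 9,
                                          min_linked = 1))
  S <- cosine_matrix(v)
  pool <- sort(unique(c(nodes[1], rep$intermediaries$node, queries)))
  score <- sapply(pool, function(n) mean(1 - S[n, queries]))
  expect_equal(rep$central, pool[which.min(score)])
})

test_that("central-protein ties break lexicographically", {
  # every pool member has mean cosine distance exactly 1 to {Q1, Q2}
  v <- rbind(AAA = c(0, 1), BBB = c(0, 1), Q1 = c(1, 0), Q2 = c(-1, 0),
             TT = c(0, -1))
  emb <- manual_embedding(v)
  g <- ppi_graph(data.frame(from = c("AAA", "BBB", "TT", "TT"),
                            to = c("Q1", "Q1", "Q1", "Q2"), weight = 0.9))
  q <- bridge_query("TT", c("Q1", "Q2"), k = 4, min_linked = 1,
                    use_mutual_knn = FALSE)
  rep <- find_intermediaries(g, emb, q)
  expect_equal(rep$central, "AAA")
  expect_equal(central_protein(rep, emb, q), "AAA")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # 20-node background, 10 carry T, all 5 members carry T
  nodes <- sprintf("G%02d", 1:20)
  ann <- stats::setNames(lapply(seq_along(nodes), function(i) {
    if (i <= 10) "T" else "U"
  }), nodes)
  g <- ppi_graph(data.frame(from = nodes[1], to = nodes[-1], weight = 0.9),
                 annotations = ann)
  res <- enrich_terms(nodes[1:5], g, background = nodes)
  row_t <- res[res$term == "T", ]
  expect_equal(row_t$p_value, hyper_upper_oracle(5, 10, 20, 5),
               tolerance = 1e-12)
  # the first term of the upper tail is C(10,5)/C(20,5)
  expect_equal(choose(10, 5) / choose(20, 5),
               dhyper(5, 10, 10, 5), tolerance = 1e-12)

  # randomized backgrounds up to 25 nodes, all terms
  set.seed(3)
  for (rep_i in 1:5) {
    N <- sample(8:25, 1)
    bg <- sprintf("H%02d", seq_len(N))
    ann <- stats::setNames(lapply(bg, function(n) {
      sample(c("T1", "T2", "T3"), sample(0:2, 1))
    }), bg)
    ann <- ann[lengths(ann) > 0]
    gg <- ppi_graph(data.frame(from = bg[1], to = bg[-1], weight = 0.9),
                    nodes = bg, annotations = ann)
    members <- sample(bg, sample(2:min(6, N), 1))
    res <- enrich_terms(members, gg, background = bg)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$p_value[i],
                   hyper_upper_oracle(res$overlap[i], res$term_size[i],
                                      N, length(members)),
                   tolerance = 1e-12)
    }
    expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-12))
  }
})

test_that("BH q-values follow the step-up formula and terms never hit are absent", {
  nodes <- c("A", "B", "C", "D")
  ann <- list(A = c("T1"), B = c("T2"), C = c("T3"), D = c("T4"))
  g <- ppi_graph(data.frame(from = "A", to = c("B", "C", "D"), weight = 0.9),
                 annotations = ann)
  res <- enrich_terms(c("A", "B", "C"), g)
  expect_false("T4" %in% res$term)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  # the documented example: p {0.01, 0.02, 0.03} -> q all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_error(enrich_terms(character(), g), "non-empty")
})

test_that("report output files are written", {
  pg <- make_planted_bridge_graph(planted_graph_spec(seed = 2))
  emb <- suppressWarnings(embed_graph(pg$graph, walk_config(seed = 2)))
  rep <- find_intermediaries(pg$graph, emb,
                             bridge_query(pg$target, pg$queries))
  dir <- tempfile()
  write_bridge_report(rep, pg$graph, dir)
  expect_true(all(file.exists(file.path(dir,
    c("intermediaries.tsv", "enrichment.tsv", "explanation_edges.tsv",
      "explanation.graphml", "run_info.txt")))))
  tsv <- read.delim(file.path(dir, "intermediaries.tsv"))
  expect_equal(tsv$node, rep$intermediaries$node)
})
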