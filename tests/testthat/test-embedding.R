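test_that("walks stay on edges and respect the determinism contract", {
  hub <- ppi_graph(data.frame(from = "H", to = c("L1", "L2", "L3"),
                              weight = 0.9))
  cfg <- walk_config(walks_per_node = 20, walk_length = 2, seed = 3)
  walks <- generate_walks(hub, cfg)
  hub_walks <- Filter(function(w) w[1] == "H", walks)
  expect_length(hub_walks, 20)
  for (w in hub_walks) expect_true(w[2] %in% c("L1", "L2", "L3"))

  expect_identical(generate_walks(hub, cfg), generate_walks(hub, cfg))
  expect_false(identical(generate_walks(hub, cfg, seed = 4),
                         generate_walks(hub, cfg, seed = 5)))
})

test_that("isolated nodes yield length-1 walks and empty graphs warn", {
  g <- ppi_graph(data.frame(from = "A", to = "B", weight = 0.9),
                 nodes = c("A", "B", "LONER"))
  walks <- generate_walks(g, walk_config(walks_per_node = 2, walk_length = 5))
  loner <- Filter(function(w) w[1] == "LONER", walks)
  expect_length(loner, 2)
  expect_true(all(lengths(loner) == 1))
  expect_warning(w0 <- generate_walks(ppi_graph()), "empty")
  expect_length(w0, 0)
})

test_that("first-step transition frequencies on a triangle are uniform", {
  tri <- ppi_graph(data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                              weight = 0.9))
  n <- 10000
  walks <- generate_walks(tri, walk_config(walks_per_node = n,
                                           walk_length = 2, seed = 1))
  firsts <- vapply(Filter(function(w) w[1] == "A", walks), `[`, "", 2L)
  # exact multinomial: each neighbour with probability 1/2, 3 sigma band
  band <- 3 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(firsts == "B") - 0.5), band)
})

test_that("node2vec return bias shifts backtracking frequency", {
  cfg_hi <- walk_config(walks_per_node = 400, walk_length = 20, p = 10,
                        q = 1, seed = 2)
  cfg_lo <- walk_config(walks_per_node = 400, walk_length = 20, p = 0.1,
                        q = 1, seed = 2)
  tri <- ppi_graph(data.frame(from = c("A", "A", "B"),
                              to = c("B", "C", "C"), weight = 0.9))
  frac_backtrack <- function(cfg) {
    walks <- generate_walks(tri, cfg)
    steps <- unlist(lapply(walks, function(w) {
      if (length(w) < 3) return(NULL)
      vapply(3:length(w), function(i) w[i] == w[i - 2], logical(1))
    }))
    mean(steps)
  }
  expect_gt(frac_backtrack(cfg_lo), frac_backtrack(cfg_hi))
})

test_that("PPMI-SVD factorization matches the hand-built 2x2 closed form", {
  corpus <- rep(list(c("A", "B")), 25)
  emb <- suppressWarnings(embed_from_walks(corpus, walk_config(dim = 2)))
  # co-occurrence [[0,25],[25,0]] -> PPMI [[0,log 2],[log 2,0]]
  M <- matrix(c(0, log(2), log(2), 0), 2)
  sv <- svd(M)
  U <- sv$u
  for (j in 1:2) if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  expected <- U %*% diag(sqrt(sv$d))
  got <- emb$vectors[c("A", "B"), ]
  expect_equal(unname(got), expected, tolerance = 1e-10)
})

test_that("vectors are finite, dim reduces with rank, and runs are deterministic", {
  tc <- two_cliques_graph()
  cfg <- walk_config(seed = 1)
  expect_warning(emb <- embed_graph(tc$graph, cfg), "reduced")
  expect_true(all(is.finite(emb$vectors)))
  expect_setequal(emb$nodes, tc$graph$nodes)
  expect_lte(ncol(emb$vectors), 64)
  emb2 <- suppressWarnings(embed_graph(tc$graph, cfg))
  expect_identical(emb$vectors, emb2$vectors)
})

test_that("two disjoint cliques separate in latent space", {
  c1 <- sprintf("A%02d", 1:8); c2 <- sprintf("C%02d", 1:8)
  cl <- function(v) { cmb <- combn(v, 2); data.frame(from = cmb[1, ], to = cmb[2, ]) }
  e <- rbind(cl(c1), cl(c2)); e$weight <- 0.9
  g <- ppi_graph(e)
  emb <- suppressWarnings(embed_graph(g, walk_config(seed = 1)))
  S <- cosine_matrix(emb$vectors)
  within <- c(S[c1, c1][upper.tri(S[c1, c1])], S[c2, c2][upper.tri(S[c2, c2])])
  expect_gt(mean(within), mean(S[c1, c2]))
})

test_that("label invariance under an order-preserving renaming", {
  tc <- two_cliques_graph(k = 4)
  g <- tc$graph
  ren <- stats::setNames(paste0("X", g$nodes), g$nodes)  # preserves order
  g2 <- ppi_graph(data.frame(from = ren[g$edges$from], to = ren[g$edges$to],
                             weight = g$edges$weight))
  cfg <- walk_config(seed = 9, dim = 8)
  e1 <- suppressWarnings(embed_graph(g, cfg))
  e2 <- suppressWarnings(embed_graph(g2, cfg))
  S1 <- cosine_matrix(e1$vectors)
  S2 <- cosine_matrix(e2$vectors)
  expect_equal(unname(S2[ren[rownames(S1)], ren[colnames(S1)]]),
               unname(S1), tolerance = 1e-9)
})

test_that("annotation block: zero for unannotated, identical for equal sets, neutral at alpha 0", {
  g <- path_graph(c("A", "B", "C"))
  g <- suppressMessages(attach_annotations(
    g, data.frame(node_id = c("A", "A", "B", "B"),
                  term_id = c("T1", "T2", "T1", "T2"))))
  emb <- suppressWarnings(embed_graph(g, walk_config(seed = 1, dim = 2)))
  aug <- append_annotation_block(emb, g, alpha = 2)
  expect_equal(aug$anno_dim, 2)
  block <- aug$vectors[, (aug$walk_dim + 1):ncol(aug$vectors), drop = FALSE]
  expect_equal(unname(block["C", ]), c(0, 0))
  expect_equal(block["A", ], block["B", ])
  expect_equal(sqrt(sum(block["A", ]^2)), 2)  # L2 norm = alpha

  zero <- append_annotation_block(emb, g, alpha = 0)
  expect_equal(cosine_matrix(zero$vectors), cosine_matrix(emb$vectors),
               tolerance = 1e-12)
})

test_that("nearest neighbours match a brute-force all-pairs sort", {
  set.seed(5)
  v <- matrix(rnorm(20 * 6), 20,
              dimnames = list(sprintf("P%02d", 1:20), NULL))
  emb <- manual_embedding(v)
  nn <- nearest_neighbours(emb, "P01", 5)
  S <- cosine_matrix(v)
  sims <- S["P01", colnames(S) != "P01"]
  ord <- order(-sims, names(sims))
  expect_equal(nn$node, names(sims)[ord][1:5])
  expect_equal(nn$similarity, unname(sims[ord][1:5]), tolerance = 1e-12)

  expect_equal(nrow(nearest_neighbours(emb, "P01", 0)), 0)
  expect_error(nearest_neighbours(emb, "NOPE", 3), "unknown")

  # duplicated vector ranks first with similarity 1
  v2 <- rbind(v, DUP = v["P01", ])
  nn2 <- nearest_neighbours(manual_embedding(v2), "P01", 1)
  expect_equal(nn2$node, "DUP")
  expect_equal(nn2$similarity, 1, tolerance = 1e-12)
})

test_that("embedding text exports round-trip the vectors", {
  v <- matrix(1:6 / 7, 3, 2, dimnames = list(c("A", "B", "C"), NULL))
  emb <- manual_embedding(v)
  tsv <- tempfile(); write_embedding(emb, tsv, "tsv")
  back <- read.delim(tsv)
  expect_equal(as.matrix(back[, -1]), unname(v), tolerance = 1e-6,
               ignore_attr = TRUE)
  w2v <- tempfile(); write_embedding(emb, w2v, "word2vec")
  expect_equal(readLines(w2v)[1], "3 2")
})
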