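# Shared fixtures and independent oracles.

# write a STRING-style edge file; rows = list of c(a, b, score) strings
write_edge_file <- function(rows, header = NULL, sep = " ") {
  path <- tempfile(fileext = ".txt")
  lines <- vapply(rows, paste, "", collapse = sep)
  writeLines(c(header, lines), path)
  path
}

# path graph A - B - C - ...
path_graph <- function(nodes, weight = 0.9) {
  n <- length(nodes)
  ppi_graph(data.frame(from = nodes[-n], to = nodes[-1], weight = weight))
}

# two k-cliques joined by one bridge node attached to one member of each
two_cliques_graph <- function(k = 8, weight = 0.9) {
  c1 <- sprintf("A%02d", seq_len(k))
  c2 <- sprintf("C%02d", seq_len(k))
  cl <- function(v) {
    cmb <- combn(v, 2)
    data.frame(from = cmb[1, ], to = cmb[2, ])
  }
  e <- rbind(cl(c1), cl(c2), data.frame(from = "BR", to = c(c1[1], c2[1])))
  e$weight <- weight
  list(graph = ppi_graph(e), clique1 = c1, clique2 = c2, bridge = "BR")
}

# hand-constructed embedding object for brute-force comparisons
manual_embedding <- function(vectors) {
  omicsbridge:::new_node_embedding(rownames(vectors), vectors)
}

# cosine similarity matrix (independent of package internals)
cosine_matrix <- function(v) {
  n <- v / sqrt(rowSums(v^2))
  n %*% t(n)
}

# hypergeometric upper-tail p by explicit combinatorial enumeration
hyper_upper_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# two-sided Fisher p by explicit point-probability enumeration over the
# support, using choose() products (independent of dhyper)
fisher_oracle <- function(tb) {
  a <- tb[1, 1]; b <- tb[1, 2]; c2 <- tb[2, 1]; d <- tb[2, 2]
  m <- a + c2; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# exact two-sided Mann-Whitney p by enumeration over value subsets,
# computing U from pairwise comparisons (not from rank sums)
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  mu <- n1 * length(y) / 2
  obs <- abs(u_of(x, y) - mu)
  sets <- combn(length(pooled), n1)
  devs <- apply(sets, 2, function(idx) {
    abs(u_of(pooled[idx], pooled[-idx]) - mu)
  })
  mean(devs >= obs - 1e-9)
}

# Ct table for a custom mini panel
mini_ct_table <- function() {
  data.frame(
    sample = rep(c("cal", "s1"), each = 3),
    group = rep(c("control", "patient"), each = 3),
    gene = rep(c("HK1", "HK2", "TG"), 2),
    ct = c(20, 20, 26,   # calibrator: dCt(TG) = 6
           20, 22, 25))  # s1: dCt(TG) = 4 -> ddCt = -2 -> RQ = 4
}
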