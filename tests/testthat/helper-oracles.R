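# Independent brute-force oracles used across tests.  These deliberately
# avoid the package's own code paths (no igraph, no vectorized scans).

# adjacency matrix from an edge data.frame over a node vector
oracle_adjacency <- function(edges, nodes) {
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$gene_a[i], edges$gene_b[i]] <- 1L
    A[edges$gene_b[i], edges$gene_a[i]] <- 1L
  }
  A
}

# mean local clustering coefficient over nodes of degree >= 2,
# by exhaustive triangle enumeration
oracle_clustering_coefficient <- function(edges, nodes) {
  A <- oracle_adjacency(edges, nodes)
  k <- rowSums(A)
  vals <- c()
  for (v in which(k >= 2)) {
    nb <- which(A[v, ] == 1L)
    tri <- 0L
    for (i in seq_along(nb)) for (j in seq_along(nb)) {
      if (i < j && A[nb[i], nb[j]] == 1L) tri <- tri + 1L
    }
    vals <- c(vals, 2 * tri / (k[v] * (k[v] - 1)))
  }
  mean(vals)
}

# neighborhood subnetwork by a naive edge scan
oracle_neighborhood <- function(edges, seeds) {
  keep <- seeds
  for (i in seq_len(nrow(edges))) {
    if (edges$gene_a[i] %in% seeds) keep <- c(keep, edges$gene_b[i])
    if (edges$gene_b[i] %in% seeds) keep <- c(keep, edges$gene_a[i])
  }
  keep <- unique(keep)
  edges[edges$gene_a %in% keep & edges$gene_b %in% keep, , drop = FALSE]
}

# naive per-window PWM scores on the plus strand of one sequence
oracle_window_scores_plus <- function(seq, mat) {
  fp <- (mat + 0.01) / 1.04
  w <- nrow(mat)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars) - w + 1
  out <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    sc <- 0
    ok <- TRUE
    for (p in seq_len(w)) {
      b <- match(chars[s + p - 1], c("A", "C", "G", "T"))
      if (is.na(b)) { ok <- FALSE; break }
      sc <- sc + log(fp[p, b] / 0.25)
    }
    if (ok) out[s] <- sc
  }
  out
}

# naive AW-box matcher, plus strand only, character by character
oracle_aw_box_plus <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  for (s in seq_len(max(0, length(chars) - 12))) {
    win <- chars[s:(s + 12)]
    if (win[1] == "C" && win[3] == "T" && win[5] == "G" &&
        win[13] %in% c("C", "G")) hits <- c(hits, s)
  }
  hits
}

# O(n^2) consensus matcher
oracle_consensus <- function(a, b) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$seq_id[i] == b$seq_id[j] && a$pwm_id[i] == b$pwm_id[j] &&
          a$strand[i] == b$strand[j] && a$start[i] == b$start[j]) {
        keep[i] <- TRUE; break
      }
    }
  }
  a[keep, , drop = FALSE]
}

# random undirected simple graph as an edge data.frame
random_graph_edges <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
             r = runif(sum(keep), 0.9, 1), stringsAsFactors = FALSE)
}

random_dna <- function(n, seed, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
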