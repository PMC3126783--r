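test_that("pairwise correlations match the covariance-formula oracle", {
  set.seed(4)
  sm <- matrix(rnorm(20 * 8), 20, dimnames = list(sprintf("g%02d", 1:20),
                                                  paste0("S", 1:8)))
  tab <- pairwise_correlation(sm)
  expect_equal(nrow(tab), choose(20, 2))
  for (i in sample(nrow(tab), 40)) {
    a <- sm[tab$gene_a[i], ]; b <- sm[tab$gene_b[i], ]
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(tab$r[i], r_oracle, tolerance = 1e-12)
  }
})

test_that("identical and opposite profiles give r of 1 and -1", {
  x <- c(1, 3, 2, 5, 4, 6, 7, 8)
  sm <- rbind(gA = x, gB = x, gC = -x)
  tab <- pairwise_correlation(sm)
  expect_equal(tab$r[tab$gene_a == "gA" & tab$gene_b == "gB"], 1)
  expect_equal(tab$r[tab$gene_a == "gA" & tab$gene_b == "gC"], -1)
  expect_error(pairwise_correlation(sm[, 1:2]), "3 stages")
})

test_that("blockwise edge computation agrees with the dense route", {
  set.seed(9)
  base <- rnorm(8)
  sm <- matrix(rnorm(60 * 8, sd = 0.4), 60) + rep(base, each = 60)
  rownames(sm) <- sprintf("g%02d", 1:60); colnames(sm) <- paste0("S", 1:8)
  dense <- pairwise_correlation(sm)
  dense <- dense[dense$r >= 0.7, ]
  block <- coexpression_edges(sm, threshold = 0.7, block_size = 13)
  key <- function(d) sort(paste(pmin(d$gene_a, d$gene_b),
                                pmax(d$gene_a, d$gene_b)))
  expect_identical(key(block), key(dense))
  expect_equal(sort(block$r), sort(dense$r), tolerance = 1e-12)
})

test_that("network construction respects the positive-r boundary rule", {
  tab <- data.frame(gene_a = c("a", "a", "b", "c"),
                    gene_b = c("b", "c", "c", "d"),
                    r = c(0.90, -0.95, 0.95, 0.89))
  net <- build_network(tab, threshold = 0.90)
  expect_equal(nrow(net$edges), 2)               # 0.90 kept, -0.95 and 0.89 not
  expect_true(any(net$edges$r == 0.90))
  expect_setequal(net$nodes, c("a", "b", "c"))
  empty <- build_network(tab[0, ], 0.9)
  expect_equal(length(empty$nodes), 0)
})

test_that("raising the threshold never adds edges or nodes", {
  set.seed(2)
  sm <- matrix(rnorm(40 * 8, sd = 1), 40) + rep(rnorm(8, sd = 2), each = 40)
  rownames(sm) <- sprintf("g%02d", 1:40); colnames(sm) <- paste0("S", 1:8)
  tab <- pairwise_correlation(sm)
  prev <- build_network(tab, 0.5)
  for (th in c(0.6, 0.7, 0.8, 0.9)) {
    cur <- build_network(tab, th)
    expect_true(all(cur$nodes %in% prev$nodes))
    expect_lte(nrow(cur$edges), nrow(prev$edges))
    prev <- cur
  }
})

test_that("Fisher Z transform gives the closed-form values", {
  fz <- fisher_z_pvalue(0.90, 8)
  expect_equal(fz$z, 1.47222, tolerance = 5e-6)
  expect_equal(fz$statistic, 3.29199, tolerance = 5e-6)
  expect_equal(fisher_z_pvalue(0, 10)$p_value, 0.5)
  expect_error(fisher_z_pvalue(1, 8), "< 1")
  expect_error(fisher_z_pvalue(0.5, 3), "n >= 4")
  # strictly decreasing in r and in n
  ps_r <- sapply(seq(0, 0.95, by = 0.05), function(r)
    fisher_z_pvalue(r, 8)$p_value)
  expect_true(all(diff(ps_r) < 0))
  ps_n <- sapply(5:30, function(n) fisher_z_pvalue(0.6, n)$p_value)
  expect_true(all(diff(ps_n) < 0))
})

test_that("clustering coefficient matches exhaustive triangle counting", {
  # K3: every node has both neighbors connected
  k3 <- build_network(data.frame(gene_a = c("a", "a", "b"),
                                 gene_b = c("b", "c", "c"), r = 0.95), 0.9)
  expect_equal(suppressWarnings(topology_stats(k3))$clustering_coefficient, 1.0)
  # 3-node path: only the center has degree >= 2, no triangle
  path <- build_network(data.frame(gene_a = c("a", "b"),
                                   gene_b = c("b", "c"), r = 0.95), 0.9)
  expect_equal(suppressWarnings(topology_stats(path))$clustering_coefficient, 0)
  # random graphs vs the O(n^3) oracle
  for (seed in 1:3) {
    edges <- random_graph_edges(60, 0.08, seed)
    net <- build_network(edges, 0.5)
    ts <- suppressWarnings(topology_stats(net))
    expect_equal(ts$clustering_coefficient,
                 oracle_clustering_coefficient(net$edges, net$nodes),
                 tolerance = 1e-12)
    # histogram counts sum to node count
    expect_equal(sum(ts$degree_histogram), ts$n_nodes)
    expect_lte(ts$degree_median, ts$degree_max)
  }
})

test_that("degree histogram uses the published bins", {
  set.seed(31)
  edges <- random_graph_edges(80, 0.5, 31)
  net <- build_network(edges, 0.5)
  ts <- suppressWarnings(topology_stats(net))
  g_deg <- table(c(net$edges$gene_a, net$edges$gene_b))
  manual <- c(sum(g_deg == 1), sum(g_deg >= 2 & g_deg <= 49),
              sum(g_deg >= 50 & g_deg <= 99), sum(g_deg >= 100 & g_deg <= 149),
              sum(g_deg >= 150 & g_deg <= 199), sum(g_deg >= 200 & g_deg <= 249),
              sum(g_deg >= 250 & g_deg <= 299), sum(g_deg >= 300))
  expect_equal(ts$degree_histogram, manual)
})

test_that("power-law fit recovers a known exponent and rejects degenerates", {
  k <- 1:100
  p <- k^-2 / sum(k^-2)
  set.seed(17)
  deg <- sample(k, 50000, replace = TRUE, prob = p)
  fit <- fit_power_law(deg)
  expect_lte(abs(fit$gamma - 2.0), 0.2)
  expect_gte(fit$r_squared, 0.95)
  expect_lte(fit$r_squared, 1)
  expect_error(fit_power_law(rep(7L, 50)), "degenerate")
})

test_that("subnetwork extraction agrees with brute-force edge scans", {
  star <- build_network(data.frame(gene_a = "hub",
                                   gene_b = paste0("leaf", 1:5), r = 0.95), 0.9)
  sub <- extract_subnetwork(star, "hub")
  expect_setequal(sub$nodes, star$nodes)         # hub neighborhood = whole star
  two_tri <- build_network(
    data.frame(gene_a = c("a", "a", "b", "x", "x", "y"),
               gene_b = c("b", "c", "c", "y", "z", "z"), r = 0.95), 0.9)
  comp <- extract_subnetwork(two_tri, "a", mode = "component")
  expect_setequal(comp$nodes, c("a", "b", "c"))
  for (seed in 4:5) {
    net <- build_network(random_graph_edges(50, 0.06, seed), 0.5)
    seeds <- net$nodes[1:3]
    sub <- extract_subnetwork(net, seeds)
    oracle <- oracle_neighborhood(net$edges, seeds)
    key <- function(d) sort(paste(d$gene_a, d$gene_b))
    expect_identical(key(sub$edges), key(oracle))
  }
  expect_warning(extract_subnetwork(star, c("hub", "ghost")), "ghost")
  suppressWarnings(expect_error(extract_subnetwork(star, "ghost"), "no seed gene"))
})

test_that("network export round-trips and formats correctly", {
  net <- build_network(data.frame(gene_a = c("a", "b"),
                                  gene_b = c("b", "c"),
                                  r = c(0.93, 0.91)), 0.9)
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_equal(readLines(sif), c("a coexp b", "b coexp c"))
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge_tsv")
  back <- read_network_tsv(tsv, threshold = 0.9)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)
  empty <- build_network(data.frame(gene_a = character(),
                                    gene_b = character(), r = numeric()), 0.9)
  export_network(empty, tsv, "edge_tsv")
  expect_equal(length(readLines(tsv)), 1)        # header only
})

test_that("anti-correlated archetypes end up in separate components", {
  arcs <- default_archetypes()[c("fa", "fa_mirror")]
  ex <- small_expression(n_genes = 100, noise_sd = 0.1, seed = 19,
                         archetypes = arcs)
  sm <- stage_medians(ex$expression)
  net <- build_network(pairwise_correlation(sm), 0.90)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
  comp <- igraph::components(g)$membership
  lab <- ex$truth$clusters$cluster[match(names(comp), ex$truth$clusters$gene)]
  # no component mixes the two archetypes
  expect_true(all(tapply(lab, comp, function(x) length(unique(x))) == 1))
})
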