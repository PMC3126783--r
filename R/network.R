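#' Pearson-threshold gene coexpression networks
#'
#' Edges connect gene pairs whose Pearson correlation across stage-median
#' profiles reaches the threshold; only positive correlations are used,
#' since positive and negative coexpression reflect different biology.
#'
#' @name coexpression
NULL

#' All pairwise Pearson correlations between gene profiles
#'
#' Genes with zero variance across stages are excluded (their correlation
#' is undefined).  Intended for small inputs and for tests; use
#' [coexpression_edges()] for large matrices.
#'
#' @param sm numeric matrix genes x stages.
#' @return data.frame (gene_a, gene_b, r), one row per unordered pair.
#' @export
pairwise_correlation <- function(sm) {
  if (ncol(sm) < 3L) stop("need >= 3 stages for correlations")
  v <- apply(sm, 1L, sd)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)")
    sm <- sm[v > 0, , drop = FALSE]
  }
  cc <- cor(t(sm))
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  data.frame(gene_a = rownames(sm)[idx[, 1L]],
             gene_b = rownames(sm)[idx[, 2L]],
             r = cc[idx], stringsAsFactors = FALSE)
}

#' Above-threshold correlation pairs, computed in gene blocks
#'
#' Streams over blocks of genes so the full dense gene x gene correlation
#' matrix is never held in memory; only pairs with r >= threshold are
#' emitted.  Scales to tens of thousands of genes.
#'
#' @param sm numeric matrix genes x stages.
#' @param threshold minimum Pearson r (default 0.90).
#' @param block_size genes per block (default 2000).
#' @return data.frame (gene_a, gene_b, r).
#' @export
coexpression_edges <- function(sm, threshold = 0.90, block_size = 2000L) {
  if (ncol(sm) < 3L) stop("need >= 3 stages for correlations")
  v <- apply(sm, 1L, sd)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)")
    sm <- sm[v > 0, , drop = FALSE]
  }
  n <- nrow(sm)
  z <- sweep(sm, 1L, rowMeans(sm))
  z <- z / sqrt(rowSums(z^2))            # rows: unit vectors; z %*% t(z) = r
  starts <- seq(1L, n, by = block_size)
  pieces <- list()
  for (a in starts) {
    ia <- a:min(a + block_size - 1L, n)
    for (b in starts[starts >= a]) {
      ib <- b:min(b + block_size - 1L, n)
      r <- z[ia, , drop = FALSE] %*% t(z[ib, , drop = FALSE])
      keep <- which(r >= threshold, arr.ind = TRUE)
      if (a == b) keep <- keep[keep[, 1L] < keep[, 2L], , drop = FALSE]
      if (nrow(keep)) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          gene_a = rownames(sm)[ia[keep[, 1L]]],
          gene_b = rownames(sm)[ib[keep[, 2L]]],
          r = r[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pieces))
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}

#' Build a coexpression network from a correlation table
#'
#' An edge is kept iff r >= threshold (boundary included; negative
#' correlations never qualify).  The node set consists of the genes
#' incident to at least one edge.  Self-pairs and duplicate pairs are
#' removed.
#'
#' @param corr data.frame (gene_a, gene_b, r) from
#'   [pairwise_correlation()] or [coexpression_edges()].
#' @param threshold correlation cutoff in (0, 1) (default 0.90).
#' @return object of class `coexpression_network` with elements `edges`
#'   (data.frame gene_a, gene_b, r), `nodes`, `threshold`.
#' @export
build_network <- function(corr, threshold = 0.90) {
  stopifnot(threshold > 0, threshold < 1)
  e <- corr[corr$r >= threshold & corr$gene_a != corr$gene_b, , drop = FALSE]
  a <- pmin(e$gene_a, e$gene_b)
  b <- pmax(e$gene_a, e$gene_b)
  e <- data.frame(gene_a = a, gene_b = b, r = e$r, stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e, nodes = sort(unique(c(e$gene_a, e$gene_b))),
                 threshold = threshold),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges (r >= %.2f)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Significance of a correlation via Fisher's Z transformation
#'
#' z = atanh(r) is approximately normal with standard error
#' 1/sqrt(n - 3); the one-sided p-value is the upper normal tail of
#' z * sqrt(n - 3).  With r = 0.90 over n = 8 stages this gives
#' p ~= 0.0005, the significance of an edge at the default threshold.
#'
#' @param r Pearson correlation, |r| < 1.
#' @param n number of paired observations, >= 4.
#' @return list (r, n, z, statistic, p_value) of class `fisher_z`.
#' @export
fisher_z_pvalue <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (n < 4) stop("need n >= 4")
  z <- atanh(r)
  stat <- z * sqrt(n - 3)
  structure(list(r = r, n = n, z = z, statistic = stat,
                 p_value = pnorm(stat, lower.tail = FALSE)),
            class = "fisher_z")
}

#' Power-law fit to a degree distribution
#'
#' Empirical degree frequencies p(k) are grouped into at most `n_bins`
#' logarithmically spaced degree bins (empty bins dropped; when there are
#' no more distinct degrees than bins, each distinct degree is its own
#' point).  Ordinary least squares of log10 p(k) on log10 k gives the
#' scale-free diagnostics: gamma = -slope and R^2, the scale-free
#' topology criterion.  An upward slope reports R^2 = 0.
#'
#' @param degrees integer vector of node degrees (values >= 1).
#' @param n_bins maximum number of log-spaced bins (default 10).
#' @return list (gamma, r_squared, fit_x, fit_y).
#' @export
fit_power_law <- function(degrees, n_bins = 10L) {
  degrees <- degrees[degrees >= 1L]
  ks <- sort(unique(degrees))
  if (length(ks) < 2L || min(ks) == max(ks))
    stop("degenerate degree sequence (all degrees equal)")
  if (length(ks) < 5L) stop("need >= 5 distinct degree values")
  pk <- as.vector(table(factor(degrees, levels = ks))) / length(degrees)
  if (length(ks) <= n_bins) {
    x <- log10(ks)
    y <- log10(pk)
  } else {
    breaks <- 10^seq(log10(min(ks)), log10(max(ks)), length.out = n_bins + 1L)
    breaks[1L] <- breaks[1L] * (1 - 1e-9)
    breaks[n_bins + 1L] <- breaks[n_bins + 1L] * (1 + 1e-9)
    bin <- cut(ks, breaks)
    x <- tapply(log10(ks), bin, mean)
    y <- log10(tapply(pk, bin, mean))
    keep <- !is.na(x) & is.finite(y)
    x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  }
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2L]]
  r2 <- summary(fit)$r.squared
  if (slope > 0) r2 <- 0
  list(gamma = -slope, r_squared = r2, fit_x = x, fit_y = y)
}

# Degree bins used for the published-style frequency histogram.
.degree_breaks <- c(0.5, 1.5, 49.5, 99.5, 149.5, 199.5, 249.5, 299.5, Inf)
.degree_labels <- c("1", "2-49", "50-99", "100-149", "150-199",
                    "200-249", "250-299", ">=300")

#' Topology diagnostics of a coexpression network
#'
#' Computes the descriptors used to characterize biological networks:
#' degree summaries, the mean clustering coefficient over nodes of degree
#' >= 2 (the local coefficient is undefined below that), the degree
#' histogram over fixed bins, and the scale-free fit from
#' [fit_power_law()] (NA with a warning when the network has fewer than 5
#' distinct degrees).
#'
#' @param net a `coexpression_network`.
#' @return list of class `topology_stats`.
#' @export
topology_stats <- function(net) {
  if (!nrow(net$edges)) stop("empty network")
  g <- as_igraph(net)
  k <- igraph::degree(g)
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc <- mean(loc[k >= 2], na.rm = TRUE)
  hist <- table(cut(k, .degree_breaks, labels = .degree_labels))
  pl <- tryCatch(fit_power_law(k),
                 error = function(e) {
                   warning("power-law fit unavailable: ", conditionMessage(e))
                   list(gamma = NA_real_, r_squared = NA_real_)
                 })
  structure(list(
    n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    degree_mean = mean(k), degree_median = median(k), degree_max = max(k),
    clustering_coefficient = cc,
    scale_free_r2 = pl$r_squared, gamma = pl$gamma,
    degree_histogram = as.vector(hist),
    degree_bins = .degree_labels), class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf(paste0("nodes %d  edges %d  mean k %.1f  median k %s  max k %d\n",
                     "clustering coefficient %.3f  scale-free R2 %s  gamma %s\n"),
              x$n_nodes, x$n_edges, x$degree_mean,
              format(x$degree_median), x$degree_max,
              x$clustering_coefficient,
              format(round(x$scale_free_r2, 3)), format(round(x$gamma, 3))))
  invisible(x)
}

#' Write topology stats as a flat key/value TSV
#'
#' @param ts a `topology_stats`.
#' @param path output path.
#' @export
write_topology_stats <- function(ts, path) {
  rows <- rbind(
    data.frame(key = c("n_nodes", "n_edges", "degree_mean", "degree_median",
                       "degree_max", "clustering_coefficient",
                       "scale_free_r2", "gamma"),
               value = c(ts$n_nodes, ts$n_edges, ts$degree_mean,
                         ts$degree_median, ts$degree_max,
                         ts$clustering_coefficient, ts$scale_free_r2,
                         ts$gamma)),
    data.frame(key = paste0("degree_hist[", ts$degree_bins, "]"),
               value = ts$degree_histogram))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a subnetwork around seed genes
#'
#' Mode "neighborhood" takes the induced subgraph on the seeds and their
#' first neighbors; mode "component" takes the union of the connected
#' components containing any seed.  Seeds absent from the network are
#' reported with a warning; it is an error if none are present.
#'
#' @param net a `coexpression_network`.
#' @param seeds character vector of seed gene ids.
#' @param mode "neighborhood" (default) or "component".
#' @return a `coexpression_network`.
#' @export
extract_subnetwork <- function(net, seeds,
                               mode = c("neighborhood", "component")) {
  mode <- match.arg(mode)
  missing <- setdiff(seeds, net$nodes)
  if (length(missing))
    warning("seed gene(s) not in network: ", paste(missing, collapse = ", "))
  seeds <- intersect(seeds, net$nodes)
  if (!length(seeds)) stop("no seed gene present in the network")
  g <- as_igraph(net)
  keep <- if (mode == "neighborhood") {
    nb <- unique(unlist(igraph::adjacent_vertices(g, seeds), use.names = FALSE))
    union(seeds, igraph::V(g)$name[nb])
  } else {
    comp <- igraph::components(g)
    igraph::V(g)$name[comp$membership %in% comp$membership[seeds]]
  }
  e <- net$edges[net$edges$gene_a %in% keep & net$edges$gene_b %in% keep, ,
                 drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e, nodes = sort(intersect(net$nodes, keep)),
                 threshold = net$threshold),
            class = "coexpression_network")
}

#' Export a network as SIF or edge-list TSV
#'
#' SIF lines read `geneA coexp geneB`; the TSV has columns gene_a,
#' gene_b, r.  Edges are written in stable lexicographic order.
#'
#' @param net a `coexpression_network`.
#' @param path output path.
#' @param format "sif" or "edge_tsv".
#' @export
export_network <- function(net, path, format = c("sif", "edge_tsv")) {
  format <- match.arg(format)
  e <- net$edges[order(net$edges$gene_a, net$edges$gene_b), , drop = FALSE]
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$gene_a, "coexp", e$gene_b) else character(),
               path)
  } else {
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network back from an edge-list TSV
#'
#' @param path TSV written by [export_network()] with format "edge_tsv".
#' @param threshold threshold to record on the network (default: the
#'   smallest r in the file, or 0.9 for an empty file).
#' @return a `coexpression_network`.
#' @export
read_network_tsv <- function(path, threshold = NULL) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(threshold))
    threshold <- if (nrow(e)) min(e$r) else 0.9
  build_network(e, threshold = threshold)
}
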