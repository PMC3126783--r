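#' Archetypal temporal profiles of seed maturation
#'
#' Stage-profile templates (log2 scale, 8 stages) for the expression
#' patterns that dominate maturing-seed transcriptomes:
#' \describe{
#'   \item{fa}{fatty-acid-synthesis-like: steady rise from the globular
#'     stage, peak around the expanded-cotyledon stage (stage 5), then a
#'     marked decline through late maturation.}
#'   \item{oleosin}{oleosin/storage-protein-like: essentially off at the
#'     globular stage, a >1000-fold (>= 10 log2 units) jump by the next
#'     stage, then a plateau through maturation.}
#'   \item{lea}{late-embryogenesis-abundant-like: quiet early, rising
#'     steeply only in the last stages.}
#'   \item{flat}{constant (no stage effect).}
#' }
#' plus the mirror images (sign-flipped copies) of the first three.
#'
#' @return named list of numeric length-8 templates.
#' @export
default_archetypes <- function() {
  fa <- c(0, 1.5, 3.0, 4.5, 5.5, 4.5, 2.5, 1.0)
  oleosin <- c(0, 10, 10.6, 11, 11.2, 11.3, 11.3, 11.3)
  lea <- c(0, 0, 0.3, 1.0, 2.5, 4.5, 7.0, 9.0)
  list(fa = fa, oleosin = oleosin, lea = lea, flat = rep(0, 8),
       fa_mirror = -fa, oleosin_mirror = -oleosin, lea_mirror = -lea)
}

#' Configuration for synthetic expression data
#'
#' @param n_genes number of genes.
#' @param cluster_archetypes named list of stage-profile templates
#'   (log2 scale), all of length `n_stages`.
#' @param cluster_proportions simplex weights over the archetypes
#'   (default: uniform); must sum to 1 within 1e-9.
#' @param n_stages number of developmental stages (default 8).
#' @param n_replicates replicates per stage (default 3).
#' @param noise_sd sd of additive Gaussian noise on the log2 scale
#'   (default 0.25).
#' @param baseline_range range of the per-gene uniform baseline in log2
#'   units (default c(6, 12), so the presence filter at 6.0 is
#'   exercised).
#' @param seed integer seed.
#' @return list of class `synth_expr_config`.
#' @export
synthetic_expression_config <- function(n_genes,
                                        cluster_archetypes = default_archetypes()[
                                          c("fa", "oleosin", "lea",
                                            "fa_mirror", "oleosin_mirror",
                                            "lea_mirror")],
                                        cluster_proportions = NULL,
                                        n_stages = 8L, n_replicates = 3L,
                                        noise_sd = 0.25,
                                        baseline_range = c(6, 12),
                                        seed = NULL) {
  stopifnot(n_genes >= 1L, n_stages >= 2L, n_replicates >= 1L,
            noise_sd >= 0, length(baseline_range) == 2L,
            baseline_range[1L] <= baseline_range[2L])
  if (is.null(names(cluster_archetypes)))
    names(cluster_archetypes) <- paste0("archetype", seq_along(cluster_archetypes))
  lens <- lengths(cluster_archetypes)
  if (any(lens != n_stages))
    stop("template length mismatch: archetype(s) ",
         paste(names(cluster_archetypes)[lens != n_stages], collapse = ", "),
         " not of length ", n_stages)
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / length(cluster_archetypes),
                               length(cluster_archetypes))
  if (abs(sum(cluster_proportions) - 1) > 1e-9)
    stop("cluster_proportions must sum to 1")
  structure(list(n_genes = as.integer(n_genes),
                 cluster_archetypes = cluster_archetypes,
                 cluster_proportions = cluster_proportions,
                 n_stages = as.integer(n_stages),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 seed = seed),
            class = "synth_expr_config")
}

#' Generate a synthetic expression matrix with known cluster truth
#'
#' Each gene is assigned to an archetype (counts follow the configured
#' proportions by largest remainder); its value in stage s, replicate r
#' is baseline + template[s] + Normal(0, noise_sd), with the baseline
#' drawn uniformly from `baseline_range`.  Output is deterministic under
#' the config seed.
#'
#' @param config a [synthetic_expression_config()].
#' @return list with `expression` (an [expression_matrix()]) and `truth`
#'   (list with `clusters`: data.frame gene, cluster).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_expr_config"))
  arcs <- config$cluster_archetypes
  n <- config$n_genes
  # largest-remainder apportionment of genes to archetypes
  raw <- config$cluster_proportions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  labels <- rep(names(arcs), cnt)
  genes <- sprintf("g%05d", seq_len(n))
  stages <- paste0("S", seq_len(config$n_stages))
  samples <- as.vector(t(outer(stages, seq_len(config$n_replicates),
                               function(s, r) paste0(s, "_r", r))))
  design <- data.frame(sample = samples,
                       stage = rep(stages, each = config$n_replicates),
                       replicate = rep(seq_len(config$n_replicates),
                                       times = config$n_stages),
                       stringsAsFactors = FALSE)
  vals <- with_seed(config$seed, {
    baseline <- runif(n, config$baseline_range[1L], config$baseline_range[2L])
    tmpl <- do.call(rbind, arcs)[labels, , drop = FALSE]
    mean_mat <- baseline + tmpl[, rep(seq_len(config$n_stages),
                                      each = config$n_replicates)]
    mean_mat + rnorm(length(mean_mat), sd = config$noise_sd)
  })
  dimnames(vals) <- list(genes, samples)
  list(expression = expression_matrix(vals, design),
       truth = list(clusters = data.frame(gene = genes, cluster = labels,
                                          stringsAsFactors = FALSE)))
}
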