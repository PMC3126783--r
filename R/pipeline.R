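#' Pipeline configuration
#'
#' Bundles the file paths and numeric parameters of the full analysis.
#' Defaults are the field-standard settings for a replicated eight-stage
#' seed series: presence cutoff log2 6.0 in >= 3 samples, correlation
#' threshold 0.90 (positive edges only), c = 6 clusters with fuzzifier
#' m = 1.75 and 0.90 membership cores, 80\% relative-score scanning,
#' 4th-order Markov backgrounds (10 per promoter) and FDR <= 0.15.
#'
#' @param expression,design,promoters,pwms input file paths (expression
#'   TSV, design TSV, promoter FASTA, PWM text file).
#' @param out_dir output directory (created if needed).
#' @param cutoff,min_present presence filter parameters.
#' @param corr_threshold network correlation cutoff in (0, 1).
#' @param clusters,fuzzifier,core_threshold fuzzy clustering parameters.
#' @param scan_threshold relative-score cutoff in (0, 1].
#' @param markov_order,n_bg,fdr_max background/FDR caller parameters.
#' @param n_perm permutations for the stage-association test.
#' @param seed master seed; stage seeds are derived from it.
#' @param seed_genes optional character vector of subnetwork seed genes.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, design, promoters, pwms, out_dir,
                            cutoff = 6.0, min_present = 3L,
                            corr_threshold = 0.90, clusters = 6L,
                            fuzzifier = 1.75, core_threshold = 0.90,
                            scan_threshold = 0.80, markov_order = 4L,
                            n_bg = 10L, fdr_max = 0.15, n_perm = 999L,
                            seed = 1L, seed_genes = NULL) {
  if (!(corr_threshold > 0 && corr_threshold < 1))
    stop("corr_threshold must be in (0, 1)")
  if (!(scan_threshold > 0 && scan_threshold <= 1))
    stop("scan_threshold must be in (0, 1]")
  if (!(core_threshold > 0.5 && core_threshold <= 1))
    stop("core_threshold must be in (0.5, 1]")
  if (!(fdr_max > 0 && fdr_max < 1)) stop("fdr_max must be in (0, 1)")
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  if (clusters < 2L) stop("clusters must be >= 2")
  if (min_present < 1L) stop("min_present must be >= 1")
  if (n_bg < 1L) stop("n_bg must be >= 1")
  if (markov_order < 0L) stop("markov_order must be >= 0")
  structure(list(expression = expression, design = design,
                 promoters = promoters, pwms = pwms, out_dir = out_dir,
                 cutoff = cutoff, min_present = as.integer(min_present),
                 corr_threshold = corr_threshold,
                 clusters = as.integer(clusters), fuzzifier = fuzzifier,
                 core_threshold = core_threshold,
                 scan_threshold = scan_threshold,
                 markov_order = as.integer(markov_order),
                 n_bg = as.integer(n_bg), fdr_max = fdr_max,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 seed_genes = seed_genes),
            class = "pipeline_config")
}

#' Read and write pipeline configs as plain key=value text
#'
#' @param path config file path; one `key = value` per line, `#` comments
#'   allowed.  `seed_genes` is comma-separated.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1L), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1L))
  args <- as.list(vals)
  names(args) <- keys
  num <- c("cutoff", "min_present", "corr_threshold", "clusters",
           "fuzzifier", "core_threshold", "scan_threshold", "markov_order",
           "n_bg", "fdr_max", "n_perm", "seed")
  for (k in intersect(num, keys)) args[[k]] <- as.numeric(args[[k]])
  if ("seed_genes" %in% keys)
    args$seed_genes <- trimws(strsplit(args$seed_genes, ",")[[1L]])
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(v)) return(NULL)
    paste(as.character(v), collapse = ",")
  }
  keys <- setdiff(names(unclass(config)), "seed_genes")
  lines <- vapply(keys, function(k) paste(k, "=", fmt(config[[k]])),
                  character(1L))
  if (!is.null(config$seed_genes))
    lines <- c(lines, paste("seed_genes =", fmt(config$seed_genes)))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: presence filter, stage medians, sample PCA and the
#' stage-association permutation test, coexpression network with topology
#' diagnostics (and subnetwork extraction when seed genes are supplied),
#' standardization and fuzzy c-means with membership cores, then promoter
#' analysis: per-PWM relative-score scan and Markov-background FDR call,
#' two-scanner consensus, and mean-plus-SD overrepresentation.  All
#' artifacts are written under `config$out_dir`; the run is deterministic
#' under the config seed (timings aside).
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: per-stage counts, topology stats, cluster and
#'   core sizes, enriched PWM ids, elapsed seconds per stage, config echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(config = unclass(config), counts = list(), elapsed = list())
  tic <- function() proc.time()[["elapsed"]]
  stage_time <- function(name, t0) report$elapsed[[name]] <<- tic() - t0

  t0 <- tic()
  em <- read_expression(config$expression, config$design)
  expressed <- filter_expressed(em, config$cutoff, config$min_present)
  writeLines(expressed, out("expressed_genes.txt"))
  report$counts$genes_total <- nrow(em$values)
  report$counts$samples <- ncol(em$values)
  report$counts$genes_expressed <- length(expressed)
  ef <- expression_matrix(em$values[expressed, , drop = FALSE], em$design)
  stage_time("filter", t0)

  t0 <- tic()
  sm <- stage_medians(ef)
  write.table(data.frame(gene = rownames(sm), sm, check.names = FALSE),
              out("stage_medians.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pca <- pca_samples(ef)
  pc_tab <- data.frame(sample = rownames(pca$scores), pca$scores,
                       check.names = FALSE)
  con <- file(out("pca_scores.tsv"), "w")
  writeLines(paste0("# variance fractions: ",
                    paste(signif(pca$var_fraction, 4L), collapse = " ")), con)
  suppressWarnings(write.table(pc_tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  gt <- global_association_test(ef, n_perm = config$n_perm,
                                seed = config$seed + 1L)
  report$global_test <- gt[c("statistic", "n_perm", "p_value", "method")]
  stage_time("qc", t0)

  t0 <- tic()
  edges <- coexpression_edges(sm, threshold = config$corr_threshold)
  net <- build_network(edges, threshold = config$corr_threshold)
  export_network(net, out("network_edges.tsv"), format = "edge_tsv")
  export_network(net, out("network.sif"), format = "sif")
  report$counts$network_nodes <- length(net$nodes)
  report$counts$network_edges <- nrow(net$edges)
  if (nrow(net$edges)) {
    ts <- topology_stats(net)
    write_topology_stats(ts, out("topology.tsv"))
    report$topology <- ts
  }
  if (!is.null(config$seed_genes)) {
    sub <- extract_subnetwork(net, config$seed_genes, mode = "neighborhood")
    export_network(sub, out("subnetwork_edges.tsv"), format = "edge_tsv")
    report$counts$subnetwork_nodes <- length(sub$nodes)
  }
  stage_time("network", t0)

  t0 <- tic()
  std <- standardize_profiles(sm)
  fcm <- fuzzy_cmeans(std, centers = config$clusters, m = config$fuzzifier,
                      seed = config$seed + 2L)
  cores <- cluster_cores(fcm, config$core_threshold)
  write_fcm(fcm, out("memberships.tsv"), out("cluster_centers.tsv"),
            core_threshold = config$core_threshold)
  report$counts$cluster_sizes <- as.vector(table(hard_labels(fcm)))
  report$counts$core_sizes <- lengths(cores)
  stage_time("clustering", t0)

  t0 <- tic()
  proms <- read_fasta(config$promoters)
  pwms <- read_pwms(config$pwms)
  report$counts$promoters <- length(proms)
  report$counts$pwms <- length(pwms)
  model <- train_markov(proms, order = config$markov_order)
  lens <- rep(nchar(proms), each = config$n_bg)
  backgrounds <- sample_markov(model, lens, n = length(lens),
                               seed = config$seed + 3L)
  cons <- list()
  for (pid in names(pwms)) {
    rel <- scan_relative(proms, pwms[[pid]], threshold = config$scan_threshold)
    fdr <- call_fdr(proms, pwms[[pid]], model, n_bg = config$n_bg,
                    fdr_max = config$fdr_max, backgrounds = backgrounds)
    cons[[pid]] <- consensus_hits(rel, fdr)
  }
  cons <- do.call(rbind, c(cons, list(make.row.names = FALSE)))
  write_hits(cons, out("consensus_hits.tsv"))
  enr <- enrichment(cons, pwms, gene_set = names(proms))
  write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  aw <- scan_aw_box(proms)
  write.table(aw, out("aw_box_hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  report$counts$consensus_hits <- nrow(cons)
  report$counts$aw_box_hits <- nrow(aw)
  report$enriched_pwms <- enr$pwm_id[enr$overrepresented]
  report$promoter_gc <- gc_content(proms)
  stage_time("motifs", t0)

  class(report) <- "run_report"
  writeLines(format_report(report), out("report.txt"))
  report
}

format_report <- function(report) {
  c(sprintf("genes_total = %d", report$counts$genes_total),
    sprintf("genes_expressed = %d", report$counts$genes_expressed),
    sprintf("network_nodes = %d", report$counts$network_nodes),
    sprintf("network_edges = %d", report$counts$network_edges),
    if (!is.null(report$counts$subnetwork_nodes))
      sprintf("subnetwork_nodes = %d", report$counts$subnetwork_nodes),
    sprintf("global_test_p = %g", report$global_test$p_value),
    sprintf("cluster_sizes = %s",
            paste(report$counts$cluster_sizes, collapse = ",")),
    sprintf("core_sizes = %s",
            paste(report$counts$core_sizes, collapse = ",")),
    sprintf("promoters = %d", report$counts$promoters),
    sprintf("promoter_gc = %.4f", report$promoter_gc),
    sprintf("consensus_hits = %d", report$counts$consensus_hits),
    sprintf("aw_box_hits = %d", report$counts$aw_box_hits),
    sprintf("enriched_pwms = %s",
            paste(report$enriched_pwms, collapse = ",")))
}

#' @export
print.run_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Write the default synthetic fixture
#'
#' Generates the standard synthetic dataset used by the tests and the
#' documentation: 2,000 genes across 8 stages x 3 replicates drawn from
#' six well-separated archetypes (rise-peak-decline, step-plateau, late
#' rise, and their mirrors) with 0.25 log2 noise; 300 promoters of
#' 1200 bp at 33\% G+C with the first synthetic PWM planted in 60\% of
#' them; and 20 synthetic PWMs.  Ground truth (cluster labels and motif
#' placements) goes to a single TSV.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_genes,n_promoters,n_pwms fixture sizes.
#' @return invisibly, the vector of files written.
#' @export
make_fixture <- function(dir, seed = 1L, n_genes = 2000L,
                         n_promoters = 300L, n_pwms = 20L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  pwms <- synthetic_pwms(n_pwms, seed = seed + 10L)
  write_pwms(pwms, file.path(dir, "pwms.txt"))
  ec <- synthetic_expression_config(n_genes, seed = seed + 11L)
  ex <- generate_expression(ec)
  write_expression(ex$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "design.tsv"))
  # plant the sharpest (highest-information) matrix of the collection
  ic <- vapply(pwms, function(p) mean(information_content(p)), numeric(1L))
  pc <- synthetic_promoter_config(
    n_promoters,
    planted = data.frame(pwm_id = names(pwms)[which.max(ic)], fraction = 0.6,
                         strand = "both", stringsAsFactors = FALSE),
    seed = seed + 12L)
  pr <- generate_promoters(pc, pwms)
  write_fasta(pr$promoters, file.path(dir, "promoters.fasta"))
  truth <- rbind(
    data.frame(kind = "cluster", id = ex$truth$clusters$gene,
               label = ex$truth$clusters$cluster, pwm_id = NA,
               start = NA, strand = NA, stringsAsFactors = FALSE),
    data.frame(kind = "motif", id = pr$truth$placements$seq_id,
               label = NA, pwm_id = pr$truth$placements$pwm_id,
               start = pr$truth$placements$start,
               strand = pr$truth$placements$strand,
               stringsAsFactors = FALSE))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, c("expression.tsv", "design.tsv",
                             "promoters.fasta", "pwms.txt", "truth.tsv")))
}
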