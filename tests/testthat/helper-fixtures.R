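# Shared fixtures, built once per test run.

.fx <- new.env()

# small expression set: 6 archetypes, zero-ish noise optional
small_expression <- function(n_genes = 120, noise_sd = 0.1, seed = 7,
                             archetypes = NULL) {
  cfg <- if (is.null(archetypes)) {
    synthetic_expression_config(n_genes, noise_sd = noise_sd, seed = seed)
  } else {
    synthetic_expression_config(n_genes, cluster_archetypes = archetypes,
                                noise_sd = noise_sd, seed = seed)
  }
  generate_expression(cfg)
}

# on-disk default fixture (directory path), built lazily
fixture_dir <- function() {
  if (is.null(.fx$dir)) {
    d <- file.path(tempdir(), "seedcoex-fixture")
    if (!dir.exists(d)) make_fixture(d, seed = 1)
    .fx$dir <- d
  }
  .fx$dir
}

fixture_truth <- function() {
  read.delim(file.path(fixture_dir(), "truth.tsv"),
             stringsAsFactors = FALSE)
}

# heavy motif-recovery results on the default fixture, computed once and
# shared between the recovery and acceptance tests
fixture_motif_results <- function() {
  if (!is.null(.fx$motif)) return(.fx$motif)
  d <- fixture_dir()
  proms <- read_fasta(file.path(d, "promoters.fasta"))
  pwms <- read_pwms(file.path(d, "pwms.txt"))
  model <- train_markov(proms, order = 4)
  bg <- sample_markov(model, rep(nchar(proms), each = 10),
                      n = 10 * length(proms), seed = 4)
  cons <- lapply(pwms, function(p) {
    consensus_hits(scan_relative(proms, p, 0.8),
                   call_fdr(proms, p, model, n_bg = 10, backgrounds = bg))
  })
  cons <- do.call(rbind, c(cons, list(make.row.names = FALSE)))
  .fx$motif <- list(promoters = proms, pwms = pwms, consensus = cons)
  .fx$motif
}

# a sharp synthetic PWM of given width whose consensus is unambiguous
degenerate_pwm <- function(bases, id = "DEG1") {
  idx <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))
  mat <- matrix(0, length(idx), 4)
  mat[cbind(seq_along(idx), idx)] <- 1
  pwm(id, "degenerate", mat)
}
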