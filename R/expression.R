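#' Expression matrix with a stage/replicate design
#'
#' Container for a log2 expression matrix (genes x samples) together with
#' the sample-to-stage design.  Stage order is taken from first appearance
#' in the design, so non-alphabetic stage series (S9, S10, ...) keep their
#' temporal order.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param design data.frame with columns `sample` and `stage` (a `replicate`
#'   column is added if absent: the running index within each stage).
#' @return object of class `expr_matrix` with elements `values` and `design`.
#' @export
expression_matrix <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values))) stop("non-finite expression values")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample", "stage") %in% names(design)))
    stop("design needs columns 'sample' and 'stage'")
  missing <- setdiff(colnames(values), design$sample)
  if (length(missing))
    stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  if (is.null(design$replicate))
    design$replicate <- stats::ave(seq_along(design$stage), design$stage,
                                   FUN = seq_along)
  rownames(design) <- NULL
  structure(list(values = values, design = design), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, %d stages\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$stage))))
  invisible(x)
}

# Stage labels in temporal (first-appearance) order.
stage_levels <- function(em) unique(em$design$stage)

#' Read an expression matrix and its design from TSV files
#'
#' The matrix TSV has gene ids in the first column and sample ids in the
#' header; the design TSV has columns `sample` and `stage`.
#'
#' @param matrix_path,design_path file paths.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(matrix_path, design_path) {
  tab <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression TSV needs a gene column plus samples")
  genes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression cell(s) in ", matrix_path)
  rownames(vals) <- genes
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  expression_matrix(vals, design)
}

#' @rdname read_expression
#' @param em an `expr_matrix`.
#' @export
write_expression <- function(em, matrix_path, design_path) {
  out <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$design[, c("sample", "stage")], design_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Filter to expressed genes
#'
#' A gene is kept when its log2 value reaches `cutoff` (>=, so a gene at
#' exactly the cutoff counts as present) in at least `min_present` samples,
#' counted over individual samples rather than stages.
#'
#' @param em an `expr_matrix`.
#' @param cutoff log2 presence threshold (default 6.0).
#' @param min_present minimum number of present calls (default 3).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(em, cutoff = 6.0, min_present = 3L) {
  stopifnot(is.finite(cutoff), min_present >= 1L,
            min_present <= ncol(em$values))
  present <- rowSums(em$values >= cutoff)
  rownames(em$values)[present >= min_present]
}

#' Collapse replicates to per-stage medians
#'
#' @param em an `expr_matrix`.
#' @return numeric matrix genes x stages (stage order = design order).
#' @export
stage_medians <- function(em) {
  stages <- stage_levels(em)
  out <- matrix(NA_real_, nrow(em$values), length(stages),
                dimnames = list(rownames(em$values), stages))
  for (s in stages) {
    idx <- which(em$design$stage == s)
    if (!length(idx)) stop("stage with no samples: ", s)
    block <- em$values[, idx, drop = FALSE]
    out[, s] <- apply(block, 1L, median)
  }
  out
}

#' Principal component analysis of samples
#'
#' PCA of samples in gene space: each gene is centered (not scaled) and the
#' samples are projected onto the principal axes.
#'
#' @param em an `expr_matrix`.
#' @return list with `scores` (samples x components) and `var_fraction`
#'   (per-component fraction of total variance).
#' @export
pca_samples <- function(em) {
  if (ncol(em$values) < 2L) stop("PCA needs at least 2 samples")
  x <- t(em$values)                      # samples x genes
  if (all(apply(x, 2L, sd) == 0)) stop("total variance is zero")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, var_fraction = vf)
}

#' Permutation test of stage association for a gene set
#'
#' Tests whether the expression of a gene set varies across stages, using
#' as statistic the sum over genes of the between-stage sum of squares of
#' sample values.  Significance comes from permuting the sample stage
#' labels; the p-value is (1 + #permuted >= observed) / (n_perm + 1), so it
#' is never reported as zero.
#'
#' @param em an `expr_matrix`.
#' @param genes gene ids to test (default: all genes).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return list with `statistic`, `n_perm`, `p_value`, `seed`, `method`.
#' @export
global_association_test <- function(em, genes = NULL, n_perm = 999L,
                                    seed = NULL) {
  if (is.null(genes)) genes <- rownames(em$values)
  stopifnot(all(genes %in% rownames(em$values)), n_perm >= 99L)
  x <- em$values[genes, , drop = FALSE]
  grp <- factor(em$design$stage, levels = stage_levels(em))
  if (nlevels(grp) < 2L) stop("need at least 2 stages")
  if (any(table(grp) == 0L)) stop("stage with zero samples")
  ns <- as.vector(table(grp))
  grand <- rowMeans(x)

  bss <- function(g) {
    sums <- t(rowsum(t(x), g))           # genes x groups
    means <- sweep(sums, 2L, ns, "/")
    sum(sweep((means - grand)^2, 2L, ns, "*"))
  }

  obs <- bss(grp)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) bss(sample(grp)), numeric(1L))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(statistic = obs, n_perm = n_perm, p_value = p, seed = seed,
       method = "permutation test, between-stage sum of squares")
}
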