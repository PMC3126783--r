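#' Standardize temporal profiles
#'
#' Per gene: subtract the mean and divide by the standard deviation, so
#' every profile has mean 0 and sd 1 and clustering sees only the shape
#' of the time course, not its absolute level.  Zero-variance (flat)
#' profiles carry no shape and are dropped with a warning.
#'
#' @param sm numeric matrix genes x stages.
#' @return standardized matrix, possibly with fewer rows.
#' @export
standardize_profiles <- function(sm) {
  v <- apply(sm, 1L, sd)
  if (all(v == 0)) stop("all profiles have zero variance")
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance profile(s)")
    sm <- sm[v > 0, , drop = FALSE]
    v <- v[v > 0]
  }
  (sm - rowMeans(sm)) / v
}

#' Fuzzy c-means clustering of expression profiles
#'
#' The standard alternating (Bezdek) iteration with Euclidean distances:
#' centers are membership-weighted means, c_i = sum_j u_ij^m x_j /
#' sum_j u_ij^m, and memberships follow u_ij = 1 / sum_k
#' (d_ij / d_kj)^(2/(m-1)).  A profile coinciding with a center gets
#' membership 1 there.  Iteration stops when the largest membership
#' change falls below `tol` or after `max_iter` sweeps.  The objective
#' J = sum_ij u_ij^m d_ij^2 is recorded every iteration and is
#' non-increasing.  Memberships are initialized from a symmetric
#' Dirichlet under `seed`; cluster labels are canonicalized by the stage
#' at which each center peaks, so runs are comparable.
#'
#' @param x numeric matrix (genes x stages), typically standardized.
#' @param centers number of clusters c >= 2 (default 6).
#' @param m fuzzifier > 1 (default 1.75).
#' @param tol convergence tolerance on max |delta U| (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param seed integer seed for the initialization.
#' @return list of class `fcm_result`: `membership` (genes x clusters),
#'   `centers` (clusters x stages), `m`, `c`, `iterations`, `objective`,
#'   `objective_trace`, `seed`.
#' @export
fuzzy_cmeans <- function(x, centers = 6L, m = 1.75, tol = 1e-6,
                         max_iter = 1000L, seed = NULL) {
  stopifnot(is.matrix(x), centers >= 2L, m > 1, nrow(x) >= centers)
  n <- nrow(x); cn <- as.integer(centers)
  u <- with_seed(seed, {
    g <- matrix(rgamma(n * cn, shape = 1), nrow = n)
    g / rowSums(g)
  })
  trace <- numeric(0L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^m
    ctr <- (t(um) %*% x) / colSums(um)
    # squared Euclidean distances genes x clusters
    d2 <- outer(rowSums(x^2), rep(1, cn)) +
      outer(rep(1, n), rowSums(ctr^2)) - 2 * x %*% t(ctr)
    d2[d2 < 0] <- 0
    tmp <- d2^(-1 / (m - 1))
    u_new <- tmp / rowSums(tmp)
    # a profile on a center (d = 0), or an overflowed row when m is close
    # to 1, gets a crisp membership at its nearest center
    hit <- rowSums(d2 == 0) > 0 | !is.finite(rowSums(tmp))
    if (any(hit)) {
      u_new[hit, ] <- 0
      u_new[cbind(which(hit), max.col(-d2[hit, , drop = FALSE]))] <- 1
    }
    trace <- c(trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol || iter >= max_iter) break
  }
  # canonical label order: stage at which the center peaks, then amplitude
  peak <- apply(ctr, 1L, which.max)
  ord <- order(peak, -apply(ctr, 1L, max))
  u <- u[, ord, drop = FALSE]
  ctr <- ctr[ord, , drop = FALSE]
  colnames(u) <- rownames(ctr) <- paste0("cluster", seq_len(cn))
  rownames(u) <- rownames(x)
  colnames(ctr) <- colnames(x)
  structure(list(membership = u, centers = ctr, m = m, c = cn,
                 iterations = iter, objective = trace[length(trace)],
                 objective_trace = trace, seed = seed),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("fcm_result: %d profiles, c = %d, m = %.2f, %d iterations, J = %.4g\n",
              nrow(x$membership), x$c, x$m, x$iterations, x$objective))
  invisible(x)
}

#' Hard cluster labels from a fuzzy result
#'
#' @param res an `fcm_result`.
#' @return named integer vector of argmax cluster per gene.
#' @export
hard_labels <- function(res) {
  lab <- max.col(res$membership, ties.method = "first")
  names(lab) <- rownames(res$membership)
  lab
}

#' Cluster cores at a membership threshold
#'
#' The core of a cluster is the set of genes whose membership in it is at
#' least `core_threshold` (default 0.90).  With a threshold above 0.5 a
#' gene can belong to at most one core.
#'
#' @param res an `fcm_result`.
#' @param core_threshold membership cutoff in (0.5, 1].
#' @return named list of gene-id vectors, one per cluster.
#' @export
cluster_cores <- function(res, core_threshold = 0.90) {
  stopifnot(core_threshold > 0.5, core_threshold <= 1)
  u <- res$membership
  out <- lapply(seq_len(ncol(u)), function(j) {
    rownames(u)[u[, j] >= core_threshold]
  })
  names(out) <- colnames(u)
  out
}

#' Write fuzzy clustering outputs as TSV
#'
#' One row per gene: its memberships, hard label and core flag; centers
#' go to a second TSV (cluster x stage).
#'
#' @param res an `fcm_result`.
#' @param membership_path,centers_path output paths.
#' @param core_threshold membership cutoff for the core flag.
#' @export
write_fcm <- function(res, membership_path, centers_path,
                      core_threshold = 0.90) {
  lab <- hard_labels(res)
  core <- apply(res$membership, 1L, max) >= core_threshold
  out <- data.frame(gene = rownames(res$membership), res$membership,
                    hard_label = colnames(res$membership)[lab],
                    core = core, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, membership_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ctr <- data.frame(cluster = rownames(res$centers), res$centers,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(ctr, centers_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(membership_path)
}
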