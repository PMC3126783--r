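#' Markov background models for promoter sequence
#'
#' A `markov_model` stores, for every order 0..k, the conditional
#' distribution of the next base given the preceding context.  The
#' lower-order tables are used for the first k positions of a sequence
#' (where the full context is not yet available) and as training
#' fallbacks.
#'
#' @name markov_model
NULL

# context code: bases b1..bo (most recent last) -> 1 + sum b_j-1 over 4^.
.context_codes <- function(mat, order) {
  # mat: integer matrix, one row per window, `order` columns, oldest first
  if (order == 0L) return(rep(1L, nrow(mat)))
  code <- integer(nrow(mat))
  for (j in seq_len(order)) code <- code * 4L + (mat[, j] - 1L)
  code + 1L
}

#' Train a Markov model on sequences
#'
#' Conditional next-base frequencies with add-one smoothing over all
#' (k+1)-mers pooled across the input, plus lower-order tables for
#' sequence starts.  Windows containing N are skipped.
#'
#' @param seqs character vector of sequences.
#' @param order Markov order k >= 0 (default 4).
#' @return object of class `markov_model`.
#' @export
train_markov <- function(seqs, order = 4L) {
  stopifnot(length(seqs) > 0L, order >= 0L)
  total <- sum(nchar(seqs))
  if (total <= 4^(order + 1L))
    warning("training data (", total, " bp) is small for order ", order,
            " (4^", order + 1L, " contexts)")
  codes <- lapply(seqs, encode_dna)
  cond <- vector("list", order + 1L)
  for (o in 0:order) {
    counts <- matrix(1, nrow = 4^o, ncol = 4L)   # add-one smoothing
    for (code in codes) {
      if (length(code) < o + 1L) next
      win <- embed(code, o + 1L)                  # cols: newest..oldest
      keep <- rowSums(is.na(win)) == 0L
      win <- win[keep, , drop = FALSE]
      if (!nrow(win)) next
      ctx <- .context_codes(win[, rev(seq_len(o + 1L))[-(o + 1L)], drop = FALSE], o)
      nxt <- win[, 1L]
      for (b in 1:4) {
        sel <- nxt == b
        if (any(sel)) {
          t <- tabulate(ctx[sel], nbins = 4^o)
          counts[, b] <- counts[, b] + t
        }
      }
    }
    cond[[o + 1L]] <- counts / rowSums(counts)
  }
  structure(list(order = as.integer(order), cond = cond, iid = FALSE),
            class = "markov_model")
}

#' Markov model with a fixed base composition
#'
#' Builds a model of the requested order whose conditional distribution is
#' the same in every context: P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2.
#' Its stationary G+C content is exactly `gc`.  Used as the synthetic
#' promoter background.
#'
#' @param gc target G+C fraction in (0,1).
#' @param order Markov order (default 4).
#' @return a `markov_model`.
#' @export
markov_from_composition <- function(gc, order = 4L) {
  stopifnot(gc > 0, gc < 1, order >= 0L)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  cond <- lapply(0:order, function(o) {
    matrix(p, nrow = 4^o, ncol = 4L, byrow = TRUE)
  })
  structure(list(order = as.integer(order), cond = cond, iid = TRUE),
            class = "markov_model")
}

#' Sample sequences from a Markov model
#'
#' @param model a `markov_model`.
#' @param length integer vector of sequence lengths; recycled against `n`.
#'   With `n = length(length)` each sequence uses the matching length, so
#'   backgrounds can mirror the lengths of a promoter set.
#' @param n number of sequences (default `length(length)`).
#' @param seed integer seed; sampling is deterministic under a fixed seed.
#' @return character vector of sequences.
#' @export
sample_markov <- function(model, length, n = base::length(length),
                          seed = NULL) {
  stopifnot(inherits(model, "markov_model"), all(length >= 1L), n >= 1L)
  lens <- rep_len(as.integer(length), n)
  k <- model$order
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    if (isTRUE(model$iid)) {
      p <- model$cond[[1L]][1L, ]
      return(vapply(lens, function(L) {
        paste(sample(bases, L, replace = TRUE, prob = p), collapse = "")
      }, character(1L)))
    }
    cums <- lapply(model$cond, function(m) t(apply(m, 1L, cumsum)))
    vapply(lens, function(L) {
      out <- integer(L)
      ctx <- 0L
      for (i in seq_len(L)) {
        o <- min(i - 1L, k)
        cc <- (ctx %% 4^o) + 1L
        u <- runif(1L)
        b <- which(u <= cums[[o + 1L]][cc, ])[1L]
        out[i] <- b
        ctx <- (ctx * 4L + (b - 1L)) %% 4^k
      }
      paste(bases[out], collapse = "")
    }, character(1L))
  })
}
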