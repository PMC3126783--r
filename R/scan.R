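#' Promoter scanning with position weight matrices
#'
#' Scanning works on the log-odds score of each window against a uniform
#' background, with a 0.01 pseudocount on the frequencies:
#' S = sum over positions of log(f'/0.25), f' = (f + 0.01)/1.04.
#' The relative score min-max normalizes S between the worst and best
#' score the matrix can attain, so 1.0 is a perfect match.  Both strands
#' are scanned; minus-strand windows are scored on the reverse complement
#' and reported in plus-strand coordinates.  Windows containing N are
#' skipped.
#'
#' @name pwm_scanning
NULL

.pwm_logodds <- function(p) {
  fp <- (p$mat + 0.01) / 1.04
  lo <- log(fp / 0.25)
  list(lo = lo,
       smin = sum(log(apply(fp, 1L, min) / 0.25)),
       smax = sum(log(apply(fp, 1L, max) / 0.25)))
}

# Raw scores of every window on both strands of one encoded sequence.
# Returns data.frame(start, strand, raw); N-containing windows dropped.
.window_scores <- function(code, p, lod = .pwm_logodds(p)) {
  w <- pwm_width(p)
  L <- length(code)
  if (L < w) stop("sequence shorter than PWM width (", w, ")")
  nw <- L - w + 1L
  score_strand <- function(cd) {
    s <- numeric(nw)
    for (j in seq_len(w)) s <- s + lod$lo[j, cd[j:(nw + j - 1L)]]
    s
  }
  sp <- score_strand(code)
  rc <- 5L - rev(code)
  sm_rc <- score_strand(rc)
  # rc window j covers plus-strand start L - (j + w - 1) + 1
  sm <- sm_rc[nw:1L]                     # indexed by plus-strand start
  out <- data.frame(
    start = c(seq_len(nw), seq_len(nw)),
    strand = rep(c(1L, -1L), each = nw),
    raw = c(sp, sm))
  out[!is.na(out$raw), , drop = FALSE]
}

.empty_hits <- function() {
  data.frame(seq_id = character(), pwm_id = character(),
             tf_name = character(), start = integer(), end = integer(),
             strand = integer(), rel_score = numeric(),
             raw_score = numeric(), stringsAsFactors = FALSE)
}

.hits_from_windows <- function(win, seq_id, p, lod) {
  if (!nrow(win)) return(.empty_hits())
  rng <- lod$smax - lod$smin
  rel <- if (rng > 0) (win$raw - lod$smin) / rng else rep(1, nrow(win))
  data.frame(seq_id = seq_id, pwm_id = p$id, tf_name = p$name,
             start = win$start, end = win$start + pwm_width(p) - 1L,
             strand = win$strand, rel_score = rel, raw_score = win$raw,
             stringsAsFactors = FALSE)
}

#' Scan sequences with a PWM at a relative-score cutoff
#'
#' @param seqs named character vector of sequences (A/C/G/T/N).
#' @param p a `pwm` or a `pwm_collection` (scanned one by one).
#' @param threshold minimum relative score for a hit (default 0.80).
#' @return data.frame of hits with columns seq_id, pwm_id, tf_name,
#'   start, end, strand (+1/-1), rel_score, raw_score; coordinates are
#'   1-based relative to the promoter start on the plus strand.
#' @export
scan_relative <- function(seqs, p, threshold = 0.80) {
  if (inherits(p, "pwm_collection") || (is.list(p) && !inherits(p, "pwm"))) {
    out <- lapply(p, function(pp) scan_relative(seqs, pp, threshold))
    return(do.call(rbind, c(out, list(make.row.names = FALSE))))
  }
  stopifnot(!is.null(names(seqs)))
  lod <- .pwm_logodds(p)
  res <- lapply(names(seqs), function(id) {
    win <- .window_scores(encode_dna(seqs[[id]]), p, lod)
    h <- .hits_from_windows(win, id, p, lod)
    h[h$rel_score >= threshold, , drop = FALSE]
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Call motif hits against a Markov background at a target FDR
#'
#' For each input sequence, `n_bg` length-matched background sequences are
#' drawn from the Markov model.  Candidate raw-score thresholds are the
#' observed real-sequence window scores in descending order; at each
#' threshold t the false discovery rate is estimated as
#' (background hits at t / n_bg) / (real hits at t), and the hits at the
#' smallest admissible threshold (largest hit set with FDR <= `fdr_max`)
#' are returned.  Empty if no threshold is admissible.
#'
#' @param seqs named character vector of real sequences.
#' @param p a `pwm`.
#' @param model a `markov_model` for the background.
#' @param n_bg backgrounds per input sequence (default 10).
#' @param fdr_max FDR upper bound (default 0.15).
#' @param seed seed for background generation.
#' @param backgrounds optional pre-generated background sequences
#'   (character vector); when supplied, `model`/`n_bg`/`seed` are only
#'   used for bookkeeping and `n_bg` must match their multiplicity.
#' @return data.frame of hits as in [scan_relative()].
#' @export
call_fdr <- function(seqs, p, model, n_bg = 10L, fdr_max = 0.15,
                     seed = NULL, backgrounds = NULL) {
  stopifnot(n_bg >= 1L, !is.null(names(seqs)))
  if (is.null(backgrounds)) {
    lens <- rep(nchar(seqs), each = n_bg)
    backgrounds <- sample_markov(model, lens, n = length(lens), seed = seed)
  }
  lod <- .pwm_logodds(p)
  real <- lapply(names(seqs), function(id) {
    win <- .window_scores(encode_dna(seqs[[id]]), p, lod)
    .hits_from_windows(win, id, p, lod)
  })
  real <- do.call(rbind, c(real, list(make.row.names = FALSE)))
  if (!nrow(real)) return(.empty_hits())
  bg_raw <- unlist(lapply(backgrounds, function(s) {
    .window_scores(encode_dna(s), p, lod)$raw
  }), use.names = FALSE)

  rr <- sort(real$raw_score)
  bb <- sort(bg_raw)
  thr <- sort(unique(real$raw_score), decreasing = TRUE)
  real_ge <- length(rr) - findInterval(thr, rr, left.open = TRUE)
  bg_ge <- length(bb) - findInterval(thr, bb, left.open = TRUE)
  fdr <- (bg_ge / n_bg) / real_ge
  ok <- which(fdr <= fdr_max)
  if (!length(ok)) return(.empty_hits())
  t_star <- thr[max(ok)]                  # smallest admissible threshold
  real[real$raw_score >= t_star, , drop = FALSE]
}

#' Consensus of two hit lists
#'
#' Keeps a hit from `hits_a` iff `hits_b` contains a hit with the same
#' (sequence id, pwm id, strand, start); score fields are carried from
#' `hits_a`.  This is the two-scanner intersection rule: only sites
#' predicted by both the relative-score scan and the FDR caller survive.
#'
#' @param hits_a,hits_b hit data.frames as returned by the scanners.
#' @return data.frame, subset of `hits_a`.
#' @export
consensus_hits <- function(hits_a, hits_b) {
  key <- function(h) paste(h$seq_id, h$pwm_id, h$strand, h$start, sep = "\r")
  hits_a[key(hits_a) %in% key(hits_b), , drop = FALSE]
}

#' Motif overrepresentation by the mean-plus-SD rule
#'
#' Counts consensus hits per PWM over a gene (promoter) set and flags a
#' PWM as overrepresented when its count exceeds the mean plus one sample
#' standard deviation of the counts across all PWMs in the collection
#' (PWMs with zero hits included).
#'
#' @param hits consensus hit data.frame.
#' @param pwms the full `pwm_collection` that was scanned.
#' @param gene_set optional sequence/gene ids to restrict the hits to.
#' @return data.frame (pwm_id, tf_name, count, overrepresented) with
#'   attributes `mean` and `sd`.
#' @export
enrichment <- function(hits, pwms, gene_set = NULL) {
  ids <- vapply(pwms, function(p) p$id, character(1L))
  if (length(ids) < 2L) stop("need >= 2 PWMs for a standard deviation")
  if (!is.null(gene_set)) hits <- hits[hits$seq_id %in% gene_set, , drop = FALSE]
  counts <- as.vector(table(factor(hits$pwm_id, levels = ids)))
  mu <- mean(counts)
  sigma <- sd(counts)
  out <- data.frame(
    pwm_id = ids,
    tf_name = vapply(pwms, function(p) p$name, character(1L)),
    count = counts,
    overrepresented = counts > mu + sigma,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mean") <- mu
  attr(out, "sd") <- sigma
  out
}

#' Scan for the AW-box pattern
#'
#' Finds all matches to the WRI1-binding AW-box [CnTnG](n)7[CG] — a 13 bp
#' window with C, T, G fixed at positions 1, 3, 5, any 7 bases, then C or
#' G — on both strands.  Minus-strand matches are located on the reverse
#' complement and reported in plus-strand coordinates.
#'
#' @param seqs named character vector of sequences.
#' @return data.frame (seq_id, start, strand).
#' @export
scan_aw_box <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  match_one <- function(code) {
    L <- length(code)
    if (L < 13L) return(integer())
    i <- seq_len(L - 12L)
    cond <- code[i] == 2L & code[i + 2L] == 4L & code[i + 4L] == 3L &
      (code[i + 12L] == 2L | code[i + 12L] == 3L)
    cond[is.na(cond)] <- FALSE
    which(cond)
  }
  res <- lapply(names(seqs), function(id) {
    code <- encode_dna(seqs[[id]])
    L <- length(code)
    plus <- match_one(code)
    minus_rc <- match_one(5L - rev(code))
    minus <- L - (minus_rc + 12L) + 1L
    data.frame(seq_id = rep(id, length(plus) + length(minus)),
               start = c(plus, minus),
               strand = rep(c(1L, -1L), c(length(plus), length(minus))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Write motif hits as TSV
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
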