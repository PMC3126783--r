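#' Configuration for synthetic promoter sets
#'
#' @param n_sequences number of promoters.
#' @param length promoter length in bp (default 1200: 1000 bp upstream
#'   plus a 200 bp transcribed leader).
#' @param background_gc stationary G+C fraction of the background
#'   (default 0.33 — plant promoters are A/T rich, below 35\% G+C).
#' @param background_order Markov order of the background chain
#'   (default 4).
#' @param planted data.frame with columns `pwm_id`, `fraction` (of
#'   sequences carrying the motif, in [0,1]) and `strand` ("both",
#'   "plus" or "minus"); NULL plants nothing.
#' @param seed integer seed.
#' @return list of class `synth_prom_config`.
#' @export
synthetic_promoter_config <- function(n_sequences, length = 1200L,
                                      background_gc = 0.33,
                                      background_order = 4L,
                                      planted = NULL, seed = NULL) {
  stopifnot(n_sequences >= 1L, length >= 1L,
            background_gc > 0, background_gc < 1, background_order >= 0L)
  if (!is.null(planted)) {
    stopifnot(all(c("pwm_id", "fraction") %in% names(planted)),
              all(planted$fraction >= 0), all(planted$fraction <= 1))
    if (is.null(planted$strand)) planted$strand <- "both"
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 background_gc = background_gc,
                 background_order = as.integer(background_order),
                 planted = planted, seed = seed),
            class = "synth_prom_config")
}

# Sample one motif instance from the per-position categorical
# distributions of a PWM.
.sample_motif <- function(p) {
  bases <- c("A", "C", "G", "T")
  paste(apply(p$mat, 1L, function(f) sample(bases, 1L, prob = f)),
        collapse = "")
}

#' Generate synthetic promoters with planted motifs
#'
#' Backgrounds are sampled from a Markov chain of the configured order
#' whose stationary composition matches `background_gc` (the same
#' machinery the motif module uses for FDR backgrounds).  Each planted
#' motif is an instance drawn from the PWM's per-position distributions,
#' inserted at a uniformly chosen position — overwriting the background,
#' so coordinates stay simple — and reverse-complemented when planted on
#' the minus strand.  Placements never overlap within a sequence.
#'
#' @param config a [synthetic_promoter_config()].
#' @param pwms a `pwm_collection` containing every planted pwm_id.
#' @return list with `promoters` (named character vector,
#'   ids `synthseq_0001`...) and `truth` (list with `placements`:
#'   data.frame seq_id, pwm_id, start, strand).
#' @export
generate_promoters <- function(config, pwms = NULL) {
  stopifnot(inherits(config, "synth_prom_config"))
  planted <- config$planted
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(!is.null(pwms))
    unknown <- setdiff(planted$pwm_id, names(pwms))
    if (length(unknown))
      stop("unknown pwm_id(s): ", paste(unknown, collapse = ", "))
    widths <- vapply(pwms[planted$pwm_id], pwm_width, integer(1L))
    if (any(widths > config$length))
      stop("sequence length ", config$length,
           " shorter than motif width ", max(widths))
  }
  model <- markov_from_composition(config$background_gc,
                                   config$background_order)
  ids <- sprintf("synthseq_%04d", seq_len(config$n_sequences))
  with_seed(config$seed, {
    seqs <- sample_markov(model, config$length, n = config$n_sequences)
    names(seqs) <- ids
    placements <- data.frame(seq_id = character(), pwm_id = character(),
                             start = integer(), strand = integer(),
                             stringsAsFactors = FALSE)
    occupied <- lapply(ids, function(i) integer(0L))  # taken positions
    names(occupied) <- ids
    if (!is.null(planted) && nrow(planted)) {
      for (k in seq_len(nrow(planted))) {
        pid <- planted$pwm_id[k]
        p <- pwms[[pid]]
        w <- pwm_width(p)
        n_carry <- round(planted$fraction[k] * config$n_sequences)
        if (n_carry == 0L) next
        carriers <- sample(ids, n_carry)
        for (sid in carriers) {
          pos <- NA_integer_
          for (try in 1:50) {                    # avoid overlapping plants
            cand <- sample.int(config$length - w + 1L, 1L)
            if (!any((cand:(cand + w - 1L)) %in% occupied[[sid]])) {
              pos <- cand; break
            }
          }
          if (is.na(pos)) next
          strand <- switch(planted$strand[k],
                           plus = 1L, minus = -1L,
                           both = sample(c(1L, -1L), 1L))
          inst <- .sample_motif(p)
          if (strand == -1L) inst <- rev_comp(inst)
          substr(seqs[[sid]], pos, pos + w - 1L) <- inst
          occupied[[sid]] <- c(occupied[[sid]], pos:(pos + w - 1L))
          placements <- rbind(placements,
                              data.frame(seq_id = sid, pwm_id = pid,
                                         start = pos, strand = strand,
                                         stringsAsFactors = FALSE))
        }
      }
    }
    rownames(placements) <- NULL
    list(promoters = seqs, truth = list(placements = placements))
  })
}
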