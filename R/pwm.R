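#' Position weight matrices
#'
#' A PWM is stored as a width x 4 matrix of per-position base frequencies
#' (columns A, C, G, T), each row summing to 1, together with an identifier
#' and the transcription-factor name.  Collections are named lists of PWMs
#' keyed by id.
#'
#' @param id matrix identifier (e.g. "MA1").
#' @param name transcription-factor name.
#' @param mat numeric width x 4 matrix of frequencies; rows are
#'   renormalized to sum to 1 (must already sum to 1 within 1e-3).
#' @return object of class `pwm`.
#' @export
pwm <- function(id, name, mat) {
  mat <- as.matrix(mat)
  if (!nrow(mat)) stop("empty matrix for PWM ", id)
  if (ncol(mat) != 4L) stop("PWM ", id, " row with != 4 fields")
  if (any(mat < 0)) stop("negative frequency in PWM ", id)
  rs <- rowSums(mat)
  if (any(rs == 0) || any(abs(rs - 1) > 1e-3))
    stop("PWM ", id, " has row sums off 1 by more than 1e-3")
  mat <- mat / rs
  colnames(mat) <- c("A", "C", "G", "T")
  rownames(mat) <- NULL
  structure(list(id = id, name = name, mat = mat), class = "pwm")
}

pwm_width <- function(p) nrow(p$mat)

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), width %d, %.2f bits/position\n", x$id, x$name,
              pwm_width(x), mean(information_content(x))))
  invisible(x)
}

#' Read a PWM collection from its text format
#'
#' Each record starts with a definition line `>ID description` (the first
#' word of the description is taken as the TF name), followed by one row
#' per motif position with four whitespace-separated frequencies in the
#' order A, C, G, T; records are separated by blank lines.
#'
#' @param path file path.
#' @return named list of [pwm()] objects (class `pwm_collection`).
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  out <- list()
  id <- NULL; desc <- NULL; rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (!length(rows)) stop("empty matrix for PWM ", id)
    mat <- do.call(rbind, rows)
    name <- if (nzchar(desc)) strsplit(desc, "\\s+")[[1L]][1L] else id
    out[[id]] <<- pwm(id, name, mat)
    id <<- NULL; desc <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) { flush(); next }
    if (startsWith(ln, ">")) {
      flush()
      fields <- strsplit(sub("^>\\s*", "", ln), "\\s+")[[1L]]
      id <- fields[1L]
      desc <- paste(fields[-1L], collapse = " ")
    } else {
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (length(vals) != 4L || anyNA(vals))
        stop("PWM row with != 4 numeric fields: '", ln, "'")
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  if (!length(out)) stop("no PWMs in ", path)
  structure(out, class = "pwm_collection")
}

#' @rdname read_pwms
#' @param pwms a `pwm_collection` or list of `pwm`s.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  first <- TRUE
  for (p in pwms) {
    if (!first) writeLines("", con)
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    writeLines(apply(p$mat, 1L, function(r) paste(sprintf("%.4f", r),
                                                  collapse = "\t")), con)
    first <- FALSE
  }
  invisible(path)
}

#' Per-position information content of a PWM
#'
#' 2 - H(position) bits where H is the Shannon entropy of the base
#' frequencies (0 log 0 taken as 0); 2 bits for an invariant position,
#' 0 for a uniform one.
#'
#' @param p a `pwm`.
#' @return numeric vector, one value in [0, 2] per position.
#' @export
information_content <- function(p) {
  f <- p$mat
  h <- -rowSums(ifelse(f > 0, f * log2(f), 0))
  2 - h
}

#' Generate random synthetic PWMs
#'
#' Draws per-position base frequencies from a sparse Dirichlet so the
#' matrices are information-rich, similar to experimentally derived
#' binding profiles.  These synthetic matrices back the test fixture; they
#' correspond to no real transcription factor.
#'
#' @param n number of matrices.
#' @param width_range inclusive range of motif widths.
#' @param concentration Dirichlet concentration per base (small = sharp).
#' @param seed integer seed.
#' @return a `pwm_collection` with ids SYN01, SYN02, ...
#' @export
synthetic_pwms <- function(n, width_range = c(8L, 12L), concentration = 0.1,
                           seed = NULL) {
  stopifnot(n >= 1L, width_range[1L] >= 4L)
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n)) {
      w <- sample(width_range[1L]:width_range[2L], 1L)
      g <- matrix(rgamma(w * 4L, shape = concentration), nrow = w)
      # guard all-zero rows from extreme sparsity
      g[rowSums(g) == 0, ] <- 1
      mat <- g / rowSums(g)
      id <- sprintf("SYN%02d", i)
      out[[id]] <- pwm(id, sprintf("synthTF%02d", i), mat)
    }
    structure(out, class = "pwm_collection")
  })
}
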