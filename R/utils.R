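#' @importFrom stats cor median pnorm prcomp rgamma rnorm runif sd lm coef
#' @importFrom utils read.delim write.table head
NULL

# Run code with a temporarily-seeded RNG, restoring prior state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Integer encoding A=1 C=2 G=3 T=4, anything else (N, gaps) -> NA.
.dna_code <- local({
  tab <- rep(NA_integer_, 128L)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("a")] <- 1L
  tab[utf8ToInt("C")] <- 2L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("g")] <- 3L
  tab[utf8ToInt("T")] <- 4L; tab[utf8ToInt("t")] <- 4L
  tab
})

encode_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .dna_code[utf8ToInt(seq)]
}

decode_dna <- function(code) {
  paste(c("A", "C", "G", "T", "N")[ifelse(is.na(code), 5L, code)],
        collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings keeping the package's working
#' representation (a named character vector) in one place.
#'
#' @param path FASTA file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two hard cluster assignments, corrected for chance;
#' 1 for identical partitions (up to label permutation), ~0 for random.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Pooled G+C fraction; N excluded from numerator and denominator.

#' G+C content of a sequence set
#'
#' @param seqs character vector of sequences.
#' @return pooled fraction (G+C)/(A+C+G+T).
#' @export
gc_content <- function(seqs) {
  stopifnot(length(seqs) > 0L)
  counts <- integer(4L)
  for (s in seqs) {
    code <- encode_dna(s)
    counts <- counts + tabulate(code[!is.na(code)], nbins = 4L)
  }
  tot <- sum(counts)
  if (tot == 0L) stop("no countable (non-N) bases in input")
  (counts[2L] + counts[3L]) / tot
}
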