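#' Extract promoter sequences from a genome
#'
#' A promoter is up to `upstream` bases 5' of the transcription start
#' plus the first `utr` transcribed bases (the 5' leader, which can also
#' carry binding sites).  When the intergenic gap to the nearest upstream
#' neighbor is shorter than `upstream`, the upstream part is truncated at
#' the neighbor boundary so no coding sequence of the adjacent gene is
#' included; sequences are also clipped at chromosome ends.  Minus-strand
#' genes are reverse-complemented so every promoter reads 5' to 3'.
#'
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`
#'   (1-based position of the transcription start), `strand` ("+"/"-")
#'   and optionally `boundary`: the chromosome coordinate of the last
#'   base of the nearest upstream neighbor (NA when unconstrained).
#' @param upstream bases upstream of the TSS (default 1000).
#' @param utr transcribed leader bases to append (default 200).
#' @return named character vector of promoter sequences.
#' @export
extract_promoters <- function(genome, genes, upstream = 1000L, utr = 200L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (!is.character(genome)) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  stopifnot(!is.null(names(genome)),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  if (is.null(genes$boundary)) genes$boundary <- NA_real_
  out <- character(nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
    L <- nchar(genome[[chrom]])
    tss <- genes$tss[i]
    if (tss < 1L || tss > L)
      stop("gene ", genes$gene_id[i], " TSS off chromosome ", chrom)
    strand <- genes$strand[i]
    bnd <- genes$boundary[i]
    if (strand == "+") {
      avail <- if (is.na(bnd)) upstream else min(upstream, tss - 1L - bnd)
      from <- max(1L, tss - max(avail, 0L))
      to <- min(L, tss + utr - 1L)
      out[i] <- substr(genome[[chrom]], from, to)
    } else if (strand == "-") {
      avail <- if (is.na(bnd)) upstream else min(upstream, bnd - 1L - tss)
      from <- max(1L, tss - utr + 1L)
      to <- min(L, tss + max(avail, 0L))
      out[i] <- rev_comp(substr(genome[[chrom]], from, to))
    } else {
      stop("malformed strand for gene ", genes$gene_id[i], ": ", strand)
    }
  }
  out
}
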