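#' Count canonical k-mers in a set of sequences
#'
#' Every window of length `k` consisting solely of A/C/G/T contributes one
#' count to its canonical class; windows containing any other character (N,
#' IUPAC ambiguity codes, U, ...) contribute nothing. Sequences shorter than
#' `k` contribute nothing. Counting is case-insensitive.
#'
#' @param seqs a [Biostrings::DNAStringSet] or character vector of nucleotide
#'   sequences.
#' @param space a [kmer_space()].
#' @param counts optional numeric vector of length `space$m` to accumulate
#'   into (defaults to zeros).
#' @return numeric vector of length `space$m` of canonical class counts.
#' @export
count_kmers <- function(seqs, space, counts = NULL) {
  stopifnot(inherits(space, "kmer_space"))
  if (is.null(counts)) counts <- numeric(space$m)
  if (length(counts) != space$m) stop("'counts' must have length space$m")
  if (length(seqs) == 0L) return(counts)
  if (is.character(seqs)) {
    # tolerate arbitrary characters: anything non-ACGT becomes N, which
    # invalidates exactly the windows containing it
    seqs <- gsub("[^ACGTacgt]", "N", seqs)
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  word_counts <- Biostrings::oligonucleotideFrequency(
    seqs, width = space$k, simplify.as = "collapsed")
  agg <- rowsum(as.numeric(word_counts), space$class_of_word)
  unname(counts) + unname(agg[, 1L])
}

#' Ensemble k-mer frequency vector of a read set
#'
#' Computes the single normalized canonical k-mer frequency vector of an
#' entire metagenome: all reads are counted jointly and the counts divided by
#' their total. This is the ensemble composition the mixture model fits — no
#' read is classified individually.
#'
#' @param x a file path (FASTA or FASTQ, optionally gzipped; format
#'   auto-detected), a [Biostrings::DNAStringSet], or a character vector of
#'   sequences.
#' @param space a [kmer_space()].
#' @return an object of class `metagenome_vector` with fields `space`,
#'   `frequencies` (length-`m` vector summing to 1), `total_kmers`, `n_reads`,
#'   and `degenerate` (`TRUE`, with a warning, when no valid k-mer was
#'   observed; the frequency vector is then all zeros).
#' @examples
#' sp <- kmer_space(7)
#' pv <- profile_reads(c("AAAAAAA", "TTTTTTT"), sp)
#' pv$frequencies[1]  # 1: both reads fall in the same canonical class
#' @export
profile_reads <- function(x, space) {
  stopifnot(inherits(space, "kmer_space"))
  if (is_path(x)) x <- read_sequences(x)
  counts <- count_kmers(x, space)
  total <- sum(counts)
  degenerate <- total <= 0
  if (degenerate) {
    warning("no valid k-mers observed; returning an all-zero vector")
    freqs <- counts
  } else {
    freqs <- counts / total
  }
  structure(
    list(space = space, frequencies = freqs, total_kmers = total,
         n_reads = length(x), degenerate = degenerate),
    class = "metagenome_vector"
  )
}

#' @export
print.metagenome_vector <- function(x, ...) {
  cat(sprintf(
    "metagenome_vector: k = %d, %d reads, %.0f k-mers, %d/%d classes occupied%s\n",
    x$space$k, x$n_reads, x$total_kmers, sum(x$frequencies > 0),
    x$space$m, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
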