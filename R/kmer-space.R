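#' Canonical k-mer space
#'
#' Defines the feature space used throughout the package: the set of canonical
#' k-mer classes for a fixed word length `k`. A k-mer and its reverse
#' complement are collapsed into a single class, represented by the
#' lexicographically smaller of the two over the alphabet A < C < G < T.
#' Collapsing halves the dimension for odd `k` (no odd-length k-mer equals its
#' own reverse complement); for even `k` the 4^(k/2) palindromic words map to
#' themselves, giving dimension (4^k + 4^(k/2)) / 2.
#'
#' The object carries a precomputed map from all 4^k words (in lexicographic
#' order, matching [Biostrings::oligonucleotideFrequency()] column order) to
#' canonical class indices, so read sets can be collapsed with a single
#' `rowsum()`.
#'
#' @param k integer word length in nucleotides (k >= 1). The command-line
#'   interface restricts k to 6..8; the library does not.
#' @return an object of class `kmer_space` with fields `k`, `m` (number of
#'   canonical classes), `class_of_word` (integer vector of length 4^k mapping
#'   each word to its class in 1..m), and `class_kmer` (the canonical
#'   representative string of each class, in lexicographic order).
#' @examples
#' sp <- kmer_space(7)
#' sp$m  # 8192
#' @export
kmer_space <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("'k' must be a single integer >= 1")
  if (k > 12L)
    stop("'k' > 12 not supported (4^k word table would be too large)")
  nw <- 4L^k
  code <- 0:(nw - 1L)
  # reverse complement in code space: digits base 4 (A=0, C=1, G=2, T=3),
  # complement = 3 - digit, order reversed
  rc <- integer(nw)
  tmp <- code
  for (i in seq_len(k)) {
    digit <- tmp %% 4L
    rc <- rc * 4L + (3L - digit)
    tmp <- tmp %/% 4L
  }
  canon <- pmin(code, rc)
  reps <- sort(unique(canon))
  class_of_word <- match(canon, reps)
  m <- length(reps)
  structure(
    list(
      k = k,
      m = m,
      class_of_word = class_of_word,
      class_kmer = code_to_kmer(reps, k)
    ),
    class = "kmer_space"
  )
}

#' @export
print.kmer_space <- function(x, ...) {
  cat(sprintf("kmer_space: k = %d, %d canonical classes (of %d words)\n",
              x$k, x$m, 4L^x$k))
  invisible(x)
}

# integer codes -> k-mer strings (A=0, C=1, G=2, T=3, most significant first)
code_to_kmer <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(code), ncol = k)
  tmp <- code
  for (i in k:1) {
    out[, i] <- bases[tmp %% 4L + 1L]
    tmp <- tmp %/% 4L
  }
  apply(out, 1L, paste0, collapse = "")
}

kmer_to_code <- function(kmer) {
  # NA for any character outside ACGT (case-insensitive)
  chars <- strsplit(toupper(kmer), "", fixed = TRUE)
  vapply(chars, function(ch) {
    d <- match(ch, c("A", "C", "G", "T")) - 1L
    if (anyNA(d)) return(NA_integer_)
    code <- 0L
    for (x in d) code <- code * 4L + x
    code
  }, integer(1))
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of A/C/G/T strings (case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCATGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Canonical class index of a k-mer
#'
#' Maps a k-mer to the index of its canonical class (the class of
#' `min(kmer, revcomp(kmer))` in lexicographic order), 1-based. Returns `NA`
#' for k-mers containing any character outside A/C/G/T.
#'
#' @param kmer character vector of k-mers, each of length `space$k`.
#' @param space a [kmer_space()].
#' @return integer vector of class indices in `1..space$m`, `NA` where the
#'   k-mer contains an ambiguous base.
#' @examples
#' sp <- kmer_space(7)
#' canonical_index("AAAAAAA", sp)  # 1: lexicographically smallest class
#' canonical_index("TTTTTTT", sp)  # 1: same class as its reverse complement
#' @export
canonical_index <- function(kmer, space) {
  stopifnot(inherits(space, "kmer_space"))
  if (any(nchar(kmer) != space$k))
    stop(sprintf("k-mer length must equal space k = %d", space$k))
  code <- kmer_to_code(kmer)
  out <- rep(NA_integer_, length(code))
  ok <- !is.na(code)
  out[ok] <- space$class_of_word[code[ok] + 1L]
  out
}
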