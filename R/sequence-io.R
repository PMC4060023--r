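# a short single string naming an existing file, as opposed to a sequence
is_path <- function(x) {
  is.character(x) && length(x) == 1L && nchar(x) < 1000L && file.exists(x)
}

#' Read sequences from a FASTA or FASTQ file
#'
#' The format is auto-detected from the first non-blank character of the file
#' (`>` for FASTA, `@` for FASTQ); both plain and gzip-compressed files are
#' accepted. FASTA records may span multiple lines; FASTQ records must be
#' 4-line records. Quality strings are discarded — the profiling model uses
#' composition only.
#'
#' @param path path to a FASTA/FASTQ file, optionally gzipped.
#' @return a [Biostrings::DNAStringSet] of the sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "r")
  first <- ""
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    ln <- trimws(ln)
    if (nzchar(ln)) { first <- substr(ln, 1L, 1L); break }
  }
  close(con)
  if (first == ">") {
    Biostrings::readDNAStringSet(path, format = "fasta")
  } else if (first == "@") {
    read_fastq(path)
  } else if (first == "") {
    Biostrings::DNAStringSet()
  } else {
    stop("cannot detect FASTA/FASTQ format of ", path,
         " (first character '", first, "')")
  }
}

# line-based FASTQ parser: strict 4-line records so that malformed input is
# reported with the offending record number rather than silently truncated
read_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ %s: truncated record %d",
                 path, length(lines) %/% 4L + 1L))
  n <- length(lines) %/% 4L
  if (n == 0L) return(Biostrings::DNAStringSet())
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop(sprintf("malformed FASTQ %s: bad record %d", path, bad[1L]))
  out <- tryCatch(Biostrings::DNAStringSet(seqs),
                  error = function(e) stop("malformed FASTQ ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  names(out) <- sub("^@", "", sub("\\s.*$", "", hdr))
  out
}

#' Write reads as a 4-line-record FASTQ file
#'
#' Qualities are constant `'I'` (Phred 40) — the simulator and profiler do not
#' model base quality.
#'
#' @param reads a [Biostrings::DNAStringSet] or character vector; names become
#'   read identifiers (`read1`, `read2`, ... if unnamed).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  qual <- strrep("I", nchar(seqs))
  rec <- rbind(paste0("@", ids), seqs, "+", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rec), con)
  invisible(path)
}

#' Parse a Jellyfish text dump into a canonical count vector
#'
#' Accepts the two-column `kmer count` text dump format (one k-mer per line).
#' Counts are accumulated into canonical classes of `space`; a k-mer of the
#' wrong length is an error.
#'
#' @param path path to the dump file (optionally gzipped).
#' @param space a [kmer_space()].
#' @return integer-valued numeric vector of length `space$m`.
#' @export
read_jellyfish_dump <- function(path, space) {
  stopifnot(inherits(space, "kmer_space"))
  tab <- utils::read.table(gzfile(path), header = FALSE,
                           col.names = c("kmer", "count"),
                           colClasses = c("character", "numeric"))
  idx <- canonical_index(tab$kmer, space)
  counts <- numeric(space$m)
  keep <- !is.na(idx)
  if (any(keep)) {
    agg <- rowsum(tab$count[keep], idx[keep])
    counts[as.integer(rownames(agg))] <- agg[, 1L]
  }
  counts
}
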