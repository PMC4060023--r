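#' Taxonomic ranks used by the reference database
#'
#' Eight named ranks, broadest to narrowest. Strain is the genome-level rank:
#' aggregation at strain is the identity mapping of the genome profile.
#'
#' @return character vector of rank names.
#' @export
taxonomic_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family",
    "genus", "species", "strain")
}

DB_MAGIC <- "KMIXDB"
DB_VERSION <- 1L

#' Build a reference k-mer matrix from genome FASTA files
#'
#' Column j of the matrix is the normalized canonical k-mer frequency vector
#' of genome j, with all contigs/replicons of the genome pooled before
#' normalization — each genome is one unit regardless of how many records its
#' FASTA holds. Every column sums to 1; a genome yielding zero usable k-mers
#' is a hard error.
#'
#' Taxonomy is supplied as a sidecar table rather than parsed from FASTA
#' headers; genomes absent from the table get `"unknown"` at every rank.
#'
#' @param genomes named character vector of FASTA paths; names are the unique
#'   genome identifiers.
#' @param taxonomy `NULL`, a data.frame with a `genome_id` column plus any of
#'   the columns named by [taxonomic_ranks()], or the path of a tab-separated
#'   file with that header.
#' @param k word length (default 7).
#' @return an object of class `reference_db` with fields `space`, `matrix`
#'   (m x n, columns named by genome id), `taxonomy` (n-row data.frame of the
#'   8 ranks), `genome_ids`, and `metadata` (k, m, n, format version, build
#'   time; the build time is not serialized, so saved databases are a pure
#'   function of their inputs).
#' @export
build_reference <- function(genomes, taxonomy = NULL, k = 7) {
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("'genomes' must be a named vector; names are genome ids")
  if (anyDuplicated(ids))
    stop("duplicate genome_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  space <- kmer_space(k)
  cols <- matrix(0, nrow = space$m, ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (j in seq_along(genomes)) {
    seqs <- read_sequences(genomes[[j]])
    counts <- count_kmers(seqs, space)
    total <- sum(counts)
    if (total <= 0)
      stop("genome '", ids[j], "' yields no usable k-mers at k = ", k)
    cols[, j] <- counts / total
  }
  tax <- resolve_taxonomy(taxonomy, ids)
  new_reference_db(space, cols, tax)
}

resolve_taxonomy <- function(taxonomy, ids) {
  ranks <- taxonomic_ranks()
  tax <- data.frame(matrix("unknown", length(ids), length(ranks),
                           dimnames = list(NULL, ranks)),
                    stringsAsFactors = FALSE)
  # strain defaults to the genome id itself so that strain-level aggregation
  # is the identity even without a taxonomy table
  tax$strain <- ids
  if (is.null(taxonomy)) return(tax)
  if (is.character(taxonomy) && length(taxonomy) == 1L)
    taxonomy <- utils::read.delim(taxonomy, stringsAsFactors = FALSE,
                                  colClasses = "character")
  if (!is.data.frame(taxonomy) || !"genome_id" %in% names(taxonomy))
    stop("'taxonomy' must be a data.frame (or TSV path) with a genome_id column")
  hit <- match(ids, taxonomy$genome_id)
  for (r in intersect(ranks, names(taxonomy))) {
    val <- taxonomy[[r]][hit]
    val[is.na(val) | !nzchar(val)] <- if (r == "strain") NA else "unknown"
    keep <- !is.na(val)
    tax[[r]][keep] <- val[keep]
  }
  if (anyDuplicated(tax$strain))
    stop("strain labels must be unique per genome within a database")
  tax
}

new_reference_db <- function(space, cols, tax, created = Sys.time()) {
  sums <- colSums(cols)
  if (any(abs(sums - 1) > 1e-9))
    stop("internal error: reference columns must sum to 1")
  structure(
    list(space = space, matrix = cols, taxonomy = tax,
         genome_ids = colnames(cols),
         metadata = list(k = space$k, m = space$m, n = ncol(cols),
                         version = DB_VERSION, created = created)),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d genomes, k = %d (%d canonical classes), format v%d\n",
              x$metadata$n, x$metadata$k, x$metadata$m, x$metadata$version))
  invisible(x)
}

#' Save / load a reference database
#'
#' The on-disk container is binary and versioned: a magic string and format
#' version, then k, m, n as little-endian int32, a UTF-8 TSV block holding
#' genome ids and taxonomy, then the matrix as row-major little-endian
#' float64. `load_reference(save_reference(db, f))` reproduces the matrix
#' bit-exactly and the labels verbatim; the bytes written are a pure function
#' of the database content, so identical builds give identical files.
#'
#' @param db a `reference_db`.
#' @param path file path.
#' @return `save_reference`: `path`, invisibly. `load_reference`: the
#'   `reference_db`.
#' @export
save_reference <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(DB_MAGIC), con)
  writeBin(as.integer(c(DB_VERSION, db$metadata$k, db$metadata$m,
                        db$metadata$n)), con, size = 4L, endian = "little")
  lab <- rbind(c("genome_id", taxonomic_ranks()),
               cbind(db$genome_ids, as.matrix(db$taxonomy)))
  lab_txt <- paste0(apply(lab, 1L, paste, collapse = "\t"), collapse = "\n")
  lab_raw <- charToRaw(enc2utf8(lab_txt))
  writeBin(length(lab_raw), con, size = 4L, endian = "little")
  writeBin(lab_raw, con)
  writeBin(as.vector(t(db$matrix)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(DB_MAGIC)))
  if (!identical(magic, DB_MAGIC))
    stop("not a kmermix reference database (bad magic): ", path)
  hdr <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
  if (hdr[1L] != DB_VERSION)
    stop("unsupported database format version ", hdr[1L],
         " (this build reads v", DB_VERSION, ")")
  k <- hdr[2L]; m <- hdr[3L]; n <- hdr[4L]
  lab_len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  lab_txt <- rawToChar(readBin(con, "raw", n = lab_len))
  Encoding(lab_txt) <- "UTF-8"
  lab <- utils::read.delim(text = lab_txt, stringsAsFactors = FALSE,
                           colClasses = "character")
  vals <- readBin(con, "numeric", n = m * n, size = 8L, endian = "little")
  if (length(vals) != m * n || nrow(lab) != n)
    stop("corrupt database file: ", path)
  cols <- matrix(vals, nrow = m, ncol = n, byrow = TRUE)
  colnames(cols) <- lab$genome_id
  space <- kmer_space(k)
  if (space$m != m) stop("corrupt database file: dimension mismatch")
  new_reference_db(space, cols, lab[taxonomic_ranks()],
                   created = file.mtime(path))
}

#' Remove all genomes carrying a given taxon from a database
#'
#' Implements the leave-taxon-out ablation protocol used to probe behavior on
#' organisms absent from the reference: genomes whose label at `rank` equals
#' `value` are dropped, and reads from the removed taxon must then be
#' explained by the remaining genomes.
#'
#' @param db a `reference_db`.
#' @param rank one of [taxonomic_ranks()].
#' @param value taxon name to remove (exact match).
#' @return a `reference_db` without the matching genomes. Removing a value
#'   present in no genome returns the database unchanged; removing every
#'   genome is an error.
#' @export
ablate_reference <- function(db, rank, value) {
  stopifnot(inherits(db, "reference_db"))
  rank <- match.arg(rank, taxonomic_ranks())
  keep <- db$taxonomy[[rank]] != value
  if (all(keep)) return(db)
  if (!any(keep))
    stop("ablating ", rank, " = '", value, "' would leave an empty database")
  new_reference_db(db$space, db$matrix[, keep, drop = FALSE],
                   db$taxonomy[keep, , drop = FALSE],
                   created = db$metadata$created)
}
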