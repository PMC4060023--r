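#' Profile a metagenome against a reference database
#'
#' The full deconvolution pipeline: compute the ensemble canonical k-mer
#' frequency vector `b` of the reads, solve the regularized non-negative
#' least-squares problem `min 1/2||Ax - b||^2 + 1/2 lambda^2 ||x||^2`,
#' `x >= 0` against the reference matrix `A`, project onto the probability
#' simplex, and optionally drop trace abundances. Abundances are
#' DNA-proportions in k-mer space: no genome-length correction is applied.
#'
#' @param x reads — a file path (FASTA/FASTQ, optionally gzipped), a
#'   [Biostrings::DNAStringSet], a character vector of sequences, or a
#'   precomputed `metagenome_vector` whose k matches the database.
#' @param db a `reference_db`.
#' @param lambda Tikhonov regularization strength (default `1e-4`; 0 gives
#'   plain NNLS).
#' @param min_abundance post-hoc reporting cutoff, see [threshold_profile()].
#' @return an `abundance_profile` over the database genomes.
#' @export
profile_metagenome <- function(x, db, lambda = 1e-4, min_abundance = 0) {
  stopifnot(inherits(db, "reference_db"))
  mv <- if (inherits(x, "metagenome_vector")) x else profile_reads(x, db$space)
  if (mv$space$k != db$space$k)
    stop("k mismatch: reads profiled at k = ", mv$space$k,
         " but database built at k = ", db$space$k)
  if (mv$degenerate) {
    prof <- normalize_to_simplex(
      stats::setNames(numeric(db$metadata$n), db$genome_ids),
      lambda_used = lambda)
    return(prof)
  }
  if (db$metadata$n > db$metadata$m)
    message("note: more reference genomes (", db$metadata$n,
            ") than k-mer classes (", db$metadata$m,
            "); the solution may not be unique")
  raw <- solve_regularized(db$matrix, mv$frequencies, lambda = lambda)
  prof <- normalize_to_simplex(raw, lambda_used = lambda)
  threshold_profile(prof, min_abundance)
}

#' Aggregate genome abundances to a taxonomic rank
#'
#' The abundance of a taxon is the sum of the abundances of the genomes
#' carrying its label at that rank; `"unknown"` labels pool into a single
#' `"unknown"` entry. Aggregation is linear and conserves total mass, so the
#' sum at every rank equals the strain-level sum.
#'
#' @param profile an `abundance_profile` aligned with `db`.
#' @param db the `reference_db` the profile was computed against (supplies
#'   the taxonomy labels).
#' @param rank one of [taxonomic_ranks()].
#' @return an object of class `rank_profile`: fields `rank`, `taxa`,
#'   `abundances` (sorted descending, ties broken alphabetically), and
#'   `degenerate`.
#' @export
aggregate_profile <- function(profile, db, rank) {
  stopifnot(inherits(profile, "abundance_profile"),
            inherits(db, "reference_db"))
  if (!rank %in% taxonomic_ranks())
    stop("invalid rank '", rank, "'; valid ranks: ",
         paste(taxonomic_ranks(), collapse = ", "))
  if (length(profile$abundances) != db$metadata$n)
    stop("profile and database have different numbers of genomes")
  labels <- db$taxonomy[[rank]]
  ab <- rowsum(profile$abundances, labels)
  taxa <- rownames(ab)
  ab <- as.vector(ab)
  ord <- order(-ab, taxa)
  structure(
    list(rank = rank, taxa = taxa[ord], abundances = ab[ord],
         degenerate = profile$degenerate),
    class = "rank_profile"
  )
}

#' @export
print.rank_profile <- function(x, n = 10L, ...) {
  cat(sprintf("rank_profile [%s]: %d taxa%s\n", x$rank, length(x$taxa),
              if (x$degenerate) " [degenerate]" else ""))
  for (i in utils::head(seq_along(x$taxa), n))
    cat(sprintf("  %-30s %8.4f\n", x$taxa[i], x$abundances[i]))
  invisible(x)
}

#' Euclidean distance between two rank profiles
#'
#' The union of the taxa of both profiles is taken and missing taxa imputed
#' as 0, so profiles over different taxon sets are comparable. The distance
#' is the square root of the sum of squared per-taxon differences.
#'
#' @param p,q `rank_profile` objects at the same rank.
#' @return non-negative scalar; 0 iff the profiles are identical.
#' @export
profile_distance <- function(p, q) {
  stopifnot(inherits(p, "rank_profile"), inherits(q, "rank_profile"))
  if (p$rank != q$rank)
    stop("cannot compare profiles at different ranks ('",
         p$rank, "' vs '", q$rank, "')")
  taxa <- union(p$taxa, q$taxa)
  pv <- p$abundances[match(taxa, p$taxa)]; pv[is.na(pv)] <- 0
  qv <- q$abundances[match(taxa, q$taxa)]; qv[is.na(qv)] <- 0
  sqrt(sum((pv - qv)^2))
}

#' Write per-rank abundance reports as TSV files
#'
#' One file `<rank>.tsv` per requested rank with header `taxon	abundance`,
#' plus `profile.tsv` in long format (`rank	taxon	abundance`) over all
#' requested ranks. Abundances are printed with 6 decimal places in the
#' deterministic order of [aggregate_profile()]. A degenerate profile writes
#' a single `unknown	0.000000` sentinel row per rank.
#'
#' @param profile an `abundance_profile`.
#' @param db the matching `reference_db`.
#' @param dir output directory (created if absent).
#' @param ranks ranks to report (default all eight).
#' @return invisibly, the paths written.
#' @export
write_report <- function(profile, db, dir, ranks = taxonomic_ranks()) {
  ranks <- match.arg(ranks, taxonomic_ranks(), several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  long <- c("rank\ttaxon\tabundance")
  for (r in ranks) {
    rp <- aggregate_profile(profile, db, r)
    if (rp$degenerate || length(rp$taxa) == 0L) {
      rows <- "unknown\t0.000000"
    } else {
      rows <- sprintf("%s\t%.6f", rp$taxa, rp$abundances)
    }
    p <- file.path(dir, paste0(r, ".tsv"))
    writeLines(c("taxon\tabundance", rows), p)
    long <- c(long, paste0(r, "\t", rows))
    paths <- c(paths, p)
  }
  p <- file.path(dir, "profile.tsv")
  writeLines(long, p)
  invisible(c(paths, p))
}
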