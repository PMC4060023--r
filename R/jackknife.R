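#' Jackknife uncertainty for a metagenome profile
#'
#' Repeated half-sampling of the reads: in each replicate,
#' `floor(fraction * n_reads)` reads are drawn uniformly without replacement,
#' the full pipeline (ensemble k-mer vector, regularized NNLS, simplex
#' normalization, rank aggregation) is recomputed, and per-taxon means and
#' population standard deviations are taken across replicates. Defaults are
#' 1000 replicates of 50% of the reads. Each replicate draws its reads from
#' its own seed substream (all replicate seeds are derived once from `seed`),
#' so results are reproducible and independent of evaluation order.
#'
#' @param x reads: file path, [Biostrings::DNAStringSet], or character
#'   vector. Reads are materialized in memory (two passes are not needed).
#' @param db a `reference_db`.
#' @param fraction sampling fraction in (0, 1); default 0.5.
#' @param reps number of replicates (>= 2); default 1000.
#' @param seed integer master seed.
#' @param lambda regularization strength passed to the solver.
#' @param ranks ranks to summarize (default all eight).
#' @return a data.frame with columns `rank`, `taxon`, `mean`, `sd` (taxa
#'   ordered by descending mean within rank), and attributes `reps`,
#'   `fraction`, `seed`, `n_degenerate` (replicates that yielded no valid
#'   k-mer and were excluded).
#' @export
jackknife_profile <- function(x, db, fraction = 0.5, reps = 1000L,
                              seed = 1L, lambda = 1e-4,
                              ranks = taxonomic_ranks()) {
  stopifnot(inherits(db, "reference_db"))
  if (!(fraction > 0 && fraction < 1)) stop("'fraction' must be in (0, 1)")
  if (reps < 2L) stop("'reps' must be >= 2")
  ranks <- match.arg(ranks, taxonomic_ranks(), several.ok = TRUE)
  if (is_path(x)) x <- read_sequences(x)
  reads <- as.character(x)
  n <- length(reads)
  take <- floor(fraction * n)
  if (take < 1L) stop("too few reads (", n, ") for fraction ", fraction)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)

  # per-replicate genome-level abundance vectors; aggregation afterwards
  mat <- matrix(NA_real_, nrow = reps, ncol = db$metadata$n)
  degenerate <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    idx <- sample.int(n, take)
    counts <- count_kmers(reads[idx], db$space)
    total <- sum(counts)
    if (total <= 0) { degenerate[r] <- TRUE; next }
    raw <- solve_regularized(db$matrix, counts / total, lambda = lambda)
    prof <- normalize_to_simplex(raw, lambda_used = lambda)
    mat[r, ] <- prof$abundances
  }
  keep <- which(!degenerate)
  if (length(keep) < 2L)
    stop("fewer than 2 usable replicates (", length(keep), " of ", reps, ")")

  out <- NULL
  for (rk in ranks) {
    labels <- db$taxonomy[[rk]]
    taxa <- sort(unique(labels))
    G <- outer(labels, taxa, "==") + 0  # n_genomes x n_taxa indicator
    agg <- mat[keep, , drop = FALSE] %*% G
    colnames(agg) <- taxa
    mu <- colMeans(agg)
    sdv <- sqrt(colMeans(sweep(agg, 2L, mu)^2))  # population sd (divide by reps)
    ord <- order(-mu, colnames(agg))
    out <- rbind(out, data.frame(rank = rk, taxon = colnames(agg)[ord],
                                 mean = unname(mu[ord]), sd = unname(sdv[ord]),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  structure(out, reps = reps, fraction = fraction, seed = seed,
            n_degenerate = sum(degenerate), class = c("jackknife_summary",
                                                      class(out)))
}

#' Write a jackknife summary as TSV
#'
#' Columns `rank taxon mean sd`, 6 decimal places, deterministic order.
#'
#' @param summary a `jackknife_summary` from [jackknife_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jackknife <- function(summary, path) {
  rows <- sprintf("%s\t%s\t%.6f\t%.6f",
                  summary$rank, summary$taxon, summary$mean, summary$sd)
  writeLines(c("rank\ttaxon\tmean\tsd", rows), path)
  invisible(path)
}
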