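#' Generate a random genome sequence
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length genome length in bp (>= 1).
#' @param gc GC content in `[0, 1]` (default 0.5).
#' @param seed optional integer seed; the draw is deterministic given it.
#' @return a single nucleotide string.
#' @export
generate_genome <- function(length, gc = 0.5, seed = NULL) {
  if (length < 1) stop("'length' must be >= 1")
  if (gc < 0 || gc > 1) stop("'gc' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate shotgun reads from a genome mixture with known proportions
#'
#' Emulates a simple single-end shotgun experiment: each read's source genome
#' is drawn from `proportions`, its start position uniformly over the valid
#' windows, its strand uniformly, and substitution errors are applied i.i.d.
#' per base at `error_rate` (uniform over the three alternative bases; no
#' indels). Because the profiler estimates DNA-proportions, `proportions` is
#' the ground-truth abundance vector in read (and, for constant read length
#' and error-free ACGT reads, k-mer) space.
#'
#' @param genomes named character vector of genome sequences; names are
#'   genome ids.
#' @param proportions non-negative vector summing to 1, aligned with
#'   `genomes`.
#' @param n_reads number of reads.
#' @param read_length read length in bp; every genome must be at least this
#'   long.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return a list with `reads` (named character vector of sequences) and
#'   `truth` (data.frame `read_id`, `genome_id`).
#' @export
generate_reads <- function(genomes, proportions, n_reads,
                           read_length = 100L, error_rate = 0,
                           seed = NULL) {
  ids <- names(genomes)
  if (is.null(ids)) stop("'genomes' must be named by genome id")
  if (length(proportions) != length(genomes))
    stop("'proportions' must align with 'genomes'")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("'proportions' must be non-negative and sum to 1")
  if (error_rate < 0 || error_rate >= 1) stop("'error_rate' must be in [0, 1)")
  if (read_length < 1) stop("'read_length' must be >= 1")
  glen <- nchar(genomes)
  if (any(glen < read_length))
    stop("genome(s) shorter than read_length: ",
         paste(ids[glen < read_length], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  src <- sample.int(length(genomes), n_reads, replace = TRUE,
                    prob = proportions)
  start <- floor(stats::runif(n_reads) * (glen[src] - read_length + 1)) + 1
  reads <- substring(genomes[src], start, start + read_length - 1L)
  rev_strand <- stats::runif(n_reads) < 0.5
  reads[rev_strand] <- revcomp(reads[rev_strand])

  if (error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    chars <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                    nrow = read_length)
    hit <- which(stats::runif(length(chars)) < error_rate)
    if (length(hit)) {
      # uniform over the 3 alternatives: shift the base by 1..3 mod 4
      cur <- match(chars[hit], bases)
      chars[hit] <- bases[(cur - 1L + sample.int(3L, length(hit),
                                                 replace = TRUE)) %% 4L + 1L]
    }
    reads <- apply(chars, 2L, paste0, collapse = "")
  }
  read_ids <- sprintf("read%d", seq_len(n_reads))
  names(reads) <- read_ids
  list(reads = reads,
       truth = data.frame(read_id = read_ids, genome_id = ids[src],
                          stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic metagenome experiment
#'
#' Convenience wrapper: generates `n_genomes` random genomes, writes each as
#' a FASTA file plus a taxonomy table (each genome its own genus/species/
#' strain under a shared higher taxonomy), simulates reads at the given
#' proportions, and writes them as FASTQ with a truth TSV.
#'
#' @param dir output directory.
#' @param n_genomes number of genomes.
#' @param genome_length genome length in bp (default 50000).
#' @param gc GC content, recycled over genomes (default 0.5).
#' @param proportions simplex vector of ground-truth DNA abundances (default
#'   uniform).
#' @param n_reads number of reads (default 100000).
#' @param read_length read length (default 100).
#' @param error_rate per-base substitution rate (default 0).
#' @param seed integer seed (default 1).
#' @return a list with paths (`genome_fastas`, `taxonomy_tsv`, `reads_fastq`,
#'   `truth_tsv`) and the in-memory `genomes`, `proportions`, `truth`.
#' @export
simulate_metagenome <- function(dir, n_genomes = 5L, genome_length = 50000L,
                                gc = 0.5,
                                proportions = rep(1 / n_genomes, n_genomes),
                                n_reads = 100000L, read_length = 100L,
                                error_rate = 0, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  gc <- rep_len(gc, n_genomes)
  ids <- sprintf("sim_genome_%02d", seq_len(n_genomes))
  genomes <- vapply(seq_len(n_genomes),
                    function(i) generate_genome(genome_length, gc[i]), "")
  names(genomes) <- ids
  fasta_paths <- file.path(dir, paste0(ids, ".fasta"))
  for (i in seq_len(n_genomes))
    writeLines(c(paste0(">", ids[i]),
                 substring(genomes[i],
                           seq(1L, genome_length, 80L),
                           pmin(seq(1L, genome_length, 80L) + 79L,
                                genome_length))),
               fasta_paths[i])
  tax <- data.frame(
    genome_id = ids, kingdom = "Bacteria", phylum = "Simulota",
    class = "Simulia", order = "Simulales", family = "Simulaceae",
    genus = paste0("Genus_", ids), species = paste0("Species_", ids),
    strain = ids, stringsAsFactors = FALSE)
  tax_path <- file.path(dir, "taxonomy.tsv")
  utils::write.table(tax, tax_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sim <- generate_reads(genomes, proportions, n_reads,
                        read_length = read_length, error_rate = error_rate)
  fastq_path <- file.path(dir, "reads.fastq")
  write_fastq(sim$reads, fastq_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(genome_fastas = stats::setNames(fasta_paths, ids),
       taxonomy_tsv = tax_path, reads_fastq = fastq_path,
       truth_tsv = truth_path, genomes = genomes,
       proportions = proportions, truth = sim$truth)
}
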