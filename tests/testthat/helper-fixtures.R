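# fixtures are generated in code at test time; nothing is stored on disk

random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n),
         function(i) paste(sample(names(p), len, TRUE, prob = p),
                           collapse = ""), "")
}

write_genome_fastas <- function(dir, genomes, width = 70L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (id in names(genomes)) {
    p <- file.path(dir, paste0(id, ".fasta"))
    s <- genomes[[id]]
    starts <- seq(1L, nchar(s), width)
    writeLines(c(paste0(">", id),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))), p)
    paths[id] <- p
  }
  paths
}

# small reference database straight from in-memory sequences
make_db <- function(genomes, k = 7, taxonomy = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_genome_fastas(dir, genomes)
  build_reference(paths, taxonomy = taxonomy, k = k)
}

toy_taxonomy <- function(ids, genus = NULL, species = NULL) {
  data.frame(genome_id = ids,
             kingdom = "Bacteria", phylum = "P", class = "C", order = "O",
             family = "F",
             genus = genus %||% paste0("G_", ids),
             species = species %||% paste0("S_", ids),
             strain = ids,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
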