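test_that("reference columns are normalized genome k-mer profiles", {
  sp <- kmer_space(7)
  # single-k-mer genome: one 1.0 entry
  db1 <- make_db(c(g1 = "AAAAAAA"))
  expect_equal(dim(db1$matrix), c(8192, 1))
  expect_equal(unname(db1$matrix[1, 1]), 1)
  expect_equal(sum(db1$matrix), 1)
  # identical genome files under different ids give identical columns
  set.seed(2)
  s <- random_dna(1, 3000)
  db2 <- make_db(c(a = s, b = s))
  expect_identical(db2$matrix[, "a"], db2$matrix[, "b"])
  # columns equal profile_reads over the genome's contigs (oracle: kmer_model)
  contigs <- random_dna(3, 1500)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "multi.fasta")
  writeLines(as.vector(rbind(paste0(">ctg", 1:3), contigs)), p)
  db3 <- build_reference(c(gx = p), k = 7)
  expect_equal(db3$matrix[, 1], profile_reads(contigs, sp)$frequencies)
  expect_true(all(abs(colSums(db3$matrix) - 1) < 1e-9))
})

test_that("degenerate or duplicated genome inputs are hard build errors", {
  dir <- withr::local_tempdir()
  paths <- write_genome_fastas(dir, c(ok = "ACGTACGTACGT", bad = "NNNNNNNNNN"))
  expect_error(build_reference(paths, k = 7), "bad")
  expect_error(build_reference(setNames(paths, c("x", "x")), k = 7),
               "duplicate")
})

test_that("taxonomy sidecar is attached and defaults to unknown", {
  ids <- c("g1", "g2", "g3")
  set.seed(4)
  genomes <- setNames(random_dna(3, 2000), ids)
  tax <- toy_taxonomy(ids, genus = c("Alpha", "Alpha", "Beta"))
  db <- make_db(genomes, taxonomy = tax)
  expect_equal(db$taxonomy$genus, c("Alpha", "Alpha", "Beta"))
  expect_equal(db$taxonomy$strain, ids)
  # no taxonomy: unknown everywhere except strain = genome id
  db0 <- make_db(genomes)
  expect_true(all(db0$taxonomy$genus == "unknown"))
  expect_equal(db0$taxonomy$strain, ids)
})

test_that("save/load round-trips the database bit-exactly", {
  set.seed(6)
  ids <- c("g1", "g2", "g3")
  genomes <- setNames(random_dna(3, 2500), ids)
  db <- make_db(genomes, taxonomy = toy_taxonomy(ids))
  f <- withr::local_tempfile(fileext = ".db")
  save_reference(db, f)
  db2 <- load_reference(f)
  expect_identical(db2$matrix, db$matrix)
  expect_identical(db2$taxonomy, db$taxonomy)
  expect_identical(db2$metadata[c("k", "m", "n", "version")],
                   db$metadata[c("k", "m", "n", "version")])
  # profiling from the loaded database equals profiling from the built one
  sim <- generate_reads(genomes, c(0.5, 0.3, 0.2), 2000, seed = 8)
  expect_identical(profile_metagenome(sim$reads, db2)$abundances,
                   profile_metagenome(sim$reads, db)$abundances)
})

test_that("corrupted or foreign files are rejected with a version error", {
  f <- withr::local_tempfile(fileext = ".db")
  writeBin(charToRaw("NOTADBFILE"), f)
  expect_error(load_reference(f), "magic")
  # flip the version field of a valid file
  db <- make_db(c(g1 = "ACGTACGTACGTACG"))
  save_reference(db, f)
  raw <- readBin(f, "raw", file.size(f))
  raw[7] <- as.raw(99)
  writeBin(raw, f)
  expect_error(load_reference(f), "version")
})

test_that("ablation removes matching genomes and refuses to empty the db", {
  ids <- c("g1", "g2", "g3")
  set.seed(10)
  genomes <- setNames(random_dna(3, 2000), ids)
  db <- make_db(genomes,
                taxonomy = toy_taxonomy(ids, genus = c("Alpha", "Alpha", "Beta")))
  ab <- ablate_reference(db, "genus", "Beta")
  expect_equal(ab$metadata$n, 2)
  expect_identical(ab$genome_ids, c("g1", "g2"))
  expect_true(all(abs(colSums(ab$matrix) - 1) < 1e-9))
  # absent value: unchanged
  expect_identical(ablate_reference(db, "genus", "Gamma")$matrix, db$matrix)
  expect_error(ablate_reference(db, "kingdom", "Bacteria"), "empty")
  expect_error(ablate_reference(db, "flavor", "x"))
})

test_that("leave-species-out reprofiling still yields a simplex profile", {
  ids <- c("g1", "g2", "g3")
  set.seed(12)
  genomes <- setNames(random_dna(3, 5000), ids)
  db <- make_db(genomes, taxonomy = toy_taxonomy(ids))
  sim <- generate_reads(genomes["g1"], 1, 3000, seed = 13)
  ab <- ablate_reference(db, "species", "S_g1")
  prof <- profile_metagenome(sim$reads, ab)
  expect_equal(length(prof$abundances), 2)
  expect_true(all(prof$abundances >= 0))
  expect_equal(sum(prof$abundances), 1, tolerance = 1e-9)
})
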