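test_that("window counting follows the sliding-window contract", {
  sp <- kmer_space(7)
  counts <- count_kmers("AAAAAAAA", sp)
  expect_equal(counts[1], 2)             # two overlapping windows, one class
  expect_equal(sum(counts), 2)
  expect_equal(sum(count_kmers("ACGTAC", sp)), 0)  # shorter than k
  set.seed(3)
  s <- random_dna(1, 500)
  expect_equal(sum(count_kmers(s, sp)), 500 - 6)   # L - k + 1 windows
  # an ambiguous base invalidates exactly the windows containing it
  sp3 <- kmer_space(3)
  c3 <- count_kmers("AAANAAA", sp3)
  expect_equal(sum(c3), 2)
  expect_equal(c3[canonical_index("AAA", sp3)], 2)
  # accumulate into an existing vector
  expect_equal(sum(count_kmers("AAAAAAAA", sp, counts)), 4)
})

test_that("profile_reads normalizes the joint count vector", {
  sp <- kmer_space(7)
  pv <- profile_reads("AAAAAAA", sp)
  expect_equal(pv$frequencies[1], 1)
  expect_equal(sum(pv$frequencies), 1)
  expect_equal(pv$total_kmers, 1)
  # strand symmetry: exact equality, not approximate
  pv2 <- profile_reads(c("AAAAAAA", "TTTTTTT"), sp)
  expect_identical(pv2$frequencies, pv$frequencies)
  set.seed(7)
  reads <- random_dna(200, 80)
  expect_identical(profile_reads(reads, sp)$frequencies,
                   profile_reads(revcomp(reads), sp)$frequencies)
  # order invariance
  expect_identical(profile_reads(rev(reads), sp)$frequencies,
                   profile_reads(reads, sp)$frequencies)
  # concatenation additivity of raw counts
  expect_equal(count_kmers(reads, sp),
               count_kmers(reads[1:100], sp) + count_kmers(reads[101:200], sp))
})

test_that("a read set with no valid k-mer yields a flagged all-zero vector", {
  sp <- kmer_space(7)
  expect_warning(pv <- profile_reads(c("NNNNNNNN", "ACG"), sp), "no valid")
  expect_true(pv$degenerate)
  expect_true(all(pv$frequencies == 0))
})

test_that("FASTA/FASTQ files, plain or gzipped, give identical profiles", {
  sp <- kmer_space(6)
  set.seed(5)
  reads <- setNames(random_dna(50, 60), paste0("r", 1:50))
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "x.fastq"); write_fastq(reads, fq)
  fqgz <- file.path(dir, "x.fastq.gz"); write_fastq(reads, fqgz)
  fa <- file.path(dir, "x.fasta")
  writeLines(as.vector(rbind(paste0(">", names(reads)), reads)), fa)
  ref <- profile_reads(reads, sp)$frequencies
  for (f in c(fq, fqgz, fa))
    expect_identical(profile_reads(f, sp)$frequencies, ref, info = f)
  # multi-line FASTA
  fa2 <- file.path(dir, "multi.fasta")
  writeLines(c(">r1", substr(reads[1], 1, 30), substr(reads[1], 31, 60)), fa2)
  expect_identical(profile_reads(fa2, sp)$frequencies,
                   profile_reads(reads[1], sp)$frequencies)
})

test_that("malformed FASTQ is reported with the offending record number", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII", "@r2", "ACGT"), bad)
  expect_error(read_sequences(bad), "record 2")
  bad2 <- file.path(dir, "bad2.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), bad2)
  expect_error(read_sequences(bad2), "record 2")
  junk <- file.path(dir, "junk.txt")
  writeLines("1,2,3", junk)
  expect_error(read_sequences(junk), "format")
})

test_that("a Jellyfish-style text dump collapses to the same counts", {
  sp <- kmer_space(5)
  set.seed(9)
  reads <- random_dna(20, 40)
  counts <- count_kmers(reads, sp)
  # emit a per-word dump from an independent tally of the same reads
  words <- unlist(lapply(reads, function(s)
    substring(s, 1:(nchar(s) - 4), 5:nchar(s))))
  tab <- table(words)
  dump <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(names(tab), as.integer(tab)), dump)
  expect_equal(read_jellyfish_dump(dump, sp), counts)
})

test_that("read sampling converges to the source genome profile", {
  sp <- kmer_space(7)
  set.seed(21)
  genome <- setNames(generate_genome(50000, 0.5), "g1")
  sim <- generate_reads(genome, 1, n_reads = 10000, read_length = 100,
                        error_rate = 0)
  d <- sqrt(sum((profile_reads(sim$reads, sp)$frequencies -
                 profile_reads(unname(genome), sp)$frequencies)^2))
  expect_lt(d, 0.01)
})
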