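# kmermix

Alignment-free taxonomic profiling of shotgun metagenomes by k-mer mixture
deconvolution.

## The problem and the model

Given millions of unannotated shotgun reads from a microbial community, which
reference organisms are present and at what relative abundance? Classifying
each read individually (by alignment or by per-read composition) scales
poorly with data volume. `kmermix` instead summarizes the **entire** read set
as one *ensemble* canonical k-mer frequency vector and explains that vector
as a non-negative mixture of reference genome signatures.

Let `A ∈ R^(m×n)` be the reference matrix whose column `j` is the normalized
canonical k-mer frequency vector of reference genome `j` (m canonical k-mer
classes, n genomes; at the default k = 7, m = 4^7/2 = 8192), and let
`b ∈ R^m` be the normalized ensemble k-mer vector of the metagenome. The
abundance vector `x` solves the non-negative least squares (NNLS) problem

    min_x  1/2 ‖Ax − b‖²  +  1/2 λ² ‖x‖²,   subject to  x ≥ 0,

followed by projection onto the probability simplex (`Σ xᵢ = 1`). The NNLS
problem is solved exactly by a Lawson–Hanson active-set iteration that
terminates on the Karush–Kuhn–Tucker conditions; the Tikhonov term `λ²‖x‖²`
(implemented by augmenting `A` with `λ·I`) stabilizes the solution when
reference genomes have nearly identical k-mer compositions. Abundances are
DNA-proportions in k-mer space — no genome-length correction is applied.

Genome-level abundances are aggregated to every taxonomic rank (kingdom …
strain), and uncertainty is estimated by a jackknife: 50% of the reads are
resampled (without replacement) many times, the full profile recomputed each
time, and the per-taxon mean and standard deviation reported.

A k-mer and its reverse complement are counted as one canonical class, so
profiles are exactly strand-invariant.

## Worked example

Everything below is synthetic and self-contained: the bundled simulator
generates reference genomes and reads with known mixing proportions.

```r
library(kmermix)

# 3 random 20 kb genomes; 20,000 100 nt reads at proportions 0.5/0.3/0.2
# with a 1% per-base substitution error rate
sim_dir <- file.path(tempdir(), "demo")
sim <- simulate_metagenome(sim_dir, n_genomes = 3, genome_length = 20000,
                           proportions = c(0.5, 0.3, 0.2),
                           n_reads = 20000, read_length = 100,
                           error_rate = 0.01, seed = 42)

db   <- build_reference(sim$genome_fastas, sim$taxonomy_tsv, k = 7)
prof <- profile_metagenome(sim$reads_fastq, db)
prof
#> abundance_profile: 3 genomes, residual 0.0007994, lambda 0.0001
#>   sim_genome_01                    0.4865
#>   sim_genome_02                    0.3043
#>   sim_genome_03                    0.2092

aggregate_profile(prof, db, "genus")
#> rank_profile [genus]: 3 taxa
#>   Genus_sim_genome_01              0.4865
#>   Genus_sim_genome_02              0.3043
#>   Genus_sim_genome_03              0.2092

jk <- jackknife_profile(sim$reads_fastq, db, reps = 50, seed = 7,
                        ranks = "genus")
head(jk, 3)
#>    rank               taxon      mean          sd
#> 1 genus Genus_sim_genome_01 0.4863821 0.003668228
#> 2 genus Genus_sim_genome_02 0.3047673 0.003348835
#> 3 genus Genus_sim_genome_03 0.2088506 0.003179825
```

The estimated abundances (0.486/0.304/0.209) recover the true mixing
proportions (0.5/0.3/0.2) to within sampling noise despite the sequencing
errors; the jackknife standard deviations (~0.003) show how tightly the
estimate is determined at this read depth. The small residual norm says the
mixture model explains the observed ensemble composition almost completely.

## Command line

A thin Rscript front-end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "kmermix", package = "kmermix"))')
Rscript $CLI simulate  --out sim --n-genomes 2 --genome-length 5000 \
                       --n-reads 500 --proportions 0.7,0.3 --seed 3
Rscript $CLI build     --genomes g.tsv --taxonomy sim/taxonomy.tsv --out ref.db
Rscript $CLI profile   --query sim/reads.fastq --db ref.db --out report/
Rscript $CLI jackknife --query sim/reads.fastq --db ref.db --reps 1000 \
                       --seed 4 --out jk.tsv
Rscript $CLI distance  --a report/genus.tsv --b other/genus.tsv
```

`build` writes a versioned binary database (bit-identical for identical
inputs); `profile` writes one TSV per rank plus a long-format `profile.tsv`;
logging goes to stderr and machine-readable output to files. Exit codes
distinguish usage errors (1), unreadable inputs (2), k mismatches (3) and
degenerate profiles (4).

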