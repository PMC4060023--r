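---
title: "Profiling metagenomes by k-mer mixture deconvolution"
author: "kmermix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling metagenomes by k-mer mixture deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmermix)
```

## The model

A shotgun metagenome is a mixture: every read was drawn from one of the
genomes in the community. If the community's DNA consists of genome $j$ in
proportion $x_j$, then the expected k-mer composition of the read pool is
the same mixture of the genomes' k-mer compositions. `kmermix` exploits this
in the simplest possible way — it never classifies a read. The whole read
set is compressed into one *ensemble* frequency vector $b \in \mathbb{R}^m$
over the $m$ canonical k-mer classes, the reference genomes into a matrix
$A \in \mathbb{R}^{m \times n}$ of column-normalized signatures, and the
abundances are the solution of

$$\min_x \tfrac{1}{2}\lVert Ax - b\rVert^2 + \tfrac{1}{2}\lambda^2\lVert x\rVert^2
\quad \text{s.t.} \quad x \ge 0,$$

followed by projection onto the probability simplex
($x \leftarrow x / \sum_i x_i$).

Assumptions worth spelling out:

* **Compositional stationarity.** Reads sample their source genome roughly
  uniformly, so the genome's full-sequence k-mer signature is a good model
  for the k-mer yield of its reads. Edge effects (a read cannot start within
  $k-1$ bases of a contig end) are negligible for reads much longer than
  $k$.
* **DNA-proportion semantics.** $x$ is the fraction of community *DNA*
  attributable to each genome, not the fraction of cells. No genome-length
  correction is applied; a large genome at equal cell count gets
  proportionally more mass.
* **Closed reference.** Every read is explained by the reference genomes.
  Organisms missing from the reference have their reads absorbed by the
  compositionally closest available genomes (demonstrated by the ablation
  analysis below).

## Canonical k-mer space

Sequencers read both strands, so a k-mer and its reverse complement are the
same observation. Both are mapped to one *canonical* class, represented by
the lexicographically smaller of the pair. For odd $k$ no k-mer is its own
reverse complement and $m = 4^k/2$; for even $k$ the $4^{k/2}$ palindromes
map to themselves and $m = (4^k + 4^{k/2})/2$. Hence $m = 2080, 8192, 32896$
for $k = 6, 7, 8$. Canonicalization makes profiles exactly strand-invariant
(a property the test suite asserts with `identical()`, not a tolerance) and
halves the feature dimension.

Windows containing any character outside A/C/G/T contribute nothing; only
the windows touching an ambiguous base are lost, not the whole read.
Counting is case-insensitive, U is treated as invalid (the model is
DNA-only), and FASTQ qualities are ignored — the method uses composition
only.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 7 (CLI allows 6–8) | word length; dimension/specificity trade-off. Larger k separates close genomes better but needs more reads per class. The library accepts any $k \ge 1$. |
| `lambda` | `1e-4` | Tikhonov strength, in the same units as the unit-sum columns of $A$. See below. |
| `min_abundance` | 0 | reporting cutoff; entries below it are zeroed and the rest renormalized (threshold first, then renormalize). |
| `fraction`, `reps` | 0.5, 1000 | jackknife half-sampling fraction and replicate count. |

**Choice of `lambda`.** The solver is exact at $\lambda = 0$, but reference
databases routinely contain near-identical genomes (strains of one species),
making $A^\top A$ ill-conditioned: tiny noise in $b$ can then swing mass
arbitrarily between collinear columns. The ridge term biases such ties
toward an even split (for exactly identical columns the regularized optimum
splits mass equally — a symmetry the tests verify numerically). The default
$10^{-4}$ is small enough that well-conditioned problems are unperturbed
(the reduction test at $\lambda = 0$ and the exact-recovery test bound the
perturbation) while still breaking degeneracy. $\lVert x\rVert$ is
non-increasing in $\lambda$, which the property tests check across a grid.

**Simplex handling.** The sum-to-one constraint is enforced by post-hoc
normalization rather than inside the solver. Plain NNLS followed by
normalization is scale-consistent here because $b$ and the columns of $A$
are all unit-sum vectors, so the raw solution already sums to approximately
one; normalization removes the residual slack. A raw solution of exactly
zero (no genome explains any signal) cannot be normalized and is returned as
an all-zero profile with a `degenerate` flag, which the reports render as an
`unknown 0.000000` sentinel row.

## The solver

The active-set iteration maintains a passive set $P$ of unconstrained
coordinates. Each outer step moves the variable with the largest positive
dual $w = A^\top(b - Ax)$ into $P$ (ties broken by lowest column index, for
determinism), solves the unconstrained least-squares problem on $P$ by QR,
and walks back along the segment to the previous iterate if any passive
coordinate would go negative. Termination is the KKT certificate: on $P$ the
normal equations hold; off $P$ all duals are $\le$ tolerance. The
anti-cycling tolerance is $10\,\epsilon\,\lVert A\rVert_F$, scaled to the
problem. Rank-deficient passive sets (exactly duplicated columns at
$\lambda = 0$) are handled by zeroing the null directions of the QR solve.

Every solution is certified *independently* of the solver by
`kkt_check()` — a direct gradient computation — and, in the tests, against a
separately-written accelerated projected-gradient solver; the two routes
agree in objective value to $10^{-8}$ relative on hundreds of random
instances.

The classical setting has $m \ge n$ (many more k-mer classes than genomes;
8192 classes at $k=7$ comfortably exceeds realistic database sizes). The
library does not forbid $n > m$, but the solution is then not unique; the
profiler emits a note when asked to work in that regime.

## Jackknife uncertainty

Each replicate draws $\lfloor 0.5\,n_\text{reads}\rfloor$ reads uniformly
*without* replacement (delete-half jackknife) and recomputes the entire
pipeline: ensemble vector, regularized NNLS, normalization, aggregation.
Means and *population* standard deviations (divide by `reps`, no Bessel
correction) are reported per taxon at every rank. Replicate seeds are all
drawn up-front from the master seed, so results do not depend on evaluation
order. Replicates that end up with no valid k-mer are excluded and counted
in the `n_degenerate` attribute.

The spread measures *read-sampling* variability only — it says nothing
about reference completeness or model misspecification.

## The simulator: what it emulates and what it does not

`simulate_metagenome()` generates i.i.d.-base genomes at chosen GC content,
then single-end reads: source genome $\sim$ the ground-truth proportions,
start position uniform, strand uniform, substitution errors i.i.d. per base
(uniform over the three alternatives), constant quality, plus a read-level
truth table. This is deliberately the simplest generative process matching
the model's assumptions.

Real data differ in ways the simulator does not reproduce: genomes have
repeat structure and skewed k-mer spectra rather than i.i.d. bases;
platforms produce indels, quality-dependent error rates and coverage biases
(GC bias, origin-of-replication gradients); communities contain organisms
absent from any reference. Passing the recovery tests therefore shows the
*estimator* is correct under its own model — it does not certify accuracy on
real communities, where reference completeness is typically the dominant
error source. The ablation test probes exactly that failure mode in
controlled form: with the true species removed and a decoy sharing 95% of
its sequence present, the decoy absorbs essentially all of the mass.

## Numerical and design choices

* **Problem sizes in the checks.** The test suite and acceptance script use
  5 genomes × 50 kb with 100,000 reads for end-to-end recovery, 200 random
  instances ($m \le 30$, $n \le 6$) for the solver cross-check, and 100
  jackknife replicates at up to 100,000 reads — sizes chosen so the full
  battery completes in a couple of minutes while binomial sampling noise
  stays an order of magnitude below the asserted bounds.
* **Ground truth in k-mer space.** The simulator's truth for end-to-end
  comparisons is the *realized* read-count fraction per genome (equal-length
  ACGT reads ⇒ equal per-read k-mer yield), i.e. exactly what a
  DNA-proportion estimator should recover — not the nominal sampling
  proportions, which differ by multinomial noise.
* **Serialization.** The database file is a documented little-endian binary
  container (magic, version, k/m/n, taxonomy TSV block, row-major float64
  matrix). Bit-exact round-trip is the contract and is tested; version or
  magic mismatches are explicit errors. The in-memory object records a build
  timestamp, but the file does not, so identical inputs produce identical
  bytes.
* **Thresholding order.** `min_abundance` zeroes entries first and
  renormalizes after, so reported abundances always sum to one.
* **Aggregation conventions.** `"unknown"` labels pool into one entry;
  output is sorted by descending abundance with alphabetical tie-breaks;
  distance between profiles with different taxon sets is computed over the
  union with zeros imputed — the only convention under which the Euclidean
  distance is well-defined.
* **Degenerate inputs.** Empty read sets, all-ambiguous reads, sequences
  shorter than $k$, and cutoffs exceeding every abundance all produce
  flagged degenerate results rather than errors; truly malformed files
  (truncated FASTQ records) fail loudly with the record number.

## Known limitations

* Accuracy is bounded by reference completeness; absent organisms are
  reported as their compositionally nearest relatives, silently.
* Strain-level resolution is limited by k-mer collinearity: near-identical
  genomes are separated mostly by the ridge term's even-split prior, not by
  signal.
* The ensemble model estimates proportions only — it cannot say *which*
  reads belong to which organism.
* Memory holds the dense $m \times n$ reference and the read set; at
  $k = 8$ and thousands of genomes this is hundreds of MB, and no
  disk-backed or sparse path is provided.
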