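# Independent NNLS oracle: accelerated projected gradient (FISTA with
# objective-based restart), sharing no code with the package's active-set
# solver. Used to certify objective values on small instances.
pg_nnls <- function(A, b, max_iter = 200000L, rel_tol = 1e-14) {
  A <- as.matrix(A)
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- as.vector(crossprod(A, b))
  L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values,
           .Machine$double.eps)
  obj <- function(x) 0.5 * sum((A %*% x - b)^2)
  x <- numeric(n); y <- x; tk <- 1
  f_prev <- obj(x)
  for (i in seq_len(max_iter)) {
    x_new <- pmax(0, y - (as.vector(AtA %*% y) - Atb) / L)
    if (obj(x_new) > obj(x)) {        # restart momentum
      y <- x; tk <- 1
      x_new <- pmax(0, y - (as.vector(AtA %*% y) - Atb) / L)
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + ((tk - 1) / t_new) * (x_new - x)
    x <- x_new; tk <- t_new
    if (i %% 200L == 0L) {
      f <- obj(x)
      if (abs(f_prev - f) <= rel_tol * max(1, f_prev)) break
      f_prev <- f
    }
  }
  x
}

nnls_objective <- function(A, b, x) 0.5 * sum((as.matrix(A) %*% x - b)^2)

# brute-force enumeration of canonical k-mer classes by string operations,
# independent of the package's integer-code arithmetic
enumerate_canonical_classes <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  words <- do.call(paste0, grid)
  comp <- chartr("ACGT", "TGCA", words)
  rc <- vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
  sort(unique(pmin(words, rc)))
}
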