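#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Minimizes `1/2 * ||Ax - b||^2` subject to `x >= 0`. The active-set
#' iteration terminates when the Karush-Kuhn-Tucker conditions hold: on the
#' passive set the normal equations are satisfied, and on the active set no
#' gradient component indicates a profitable entry. The algorithm is fully
#' deterministic: the entering variable is the one with the largest negative
#' gradient, ties broken by lowest column index.
#'
#' @param A numeric matrix (m x n); all entries finite.
#' @param b numeric vector of length m; all entries finite.
#' @param tol dual-feasibility / anti-cycling tolerance. Defaults to
#'   `10 * .Machine$double.eps * norm(A, "F")`, scaled to the problem.
#' @return numeric vector `x >= 0` of length n, with attributes
#'   `residual_norm` (`||Ax - b||` at the solution) and `iterations`.
#' @examples
#' solve_nnls(diag(2), c(0.3, 0.7))  # feasible unconstrained optimum
#' @export
solve_nnls <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  if (!is.numeric(A) || !all(is.finite(A))) stop("'A' must be finite numeric")
  if (!is.numeric(b) || !all(is.finite(b))) stop("'b' must be finite numeric")
  m <- nrow(A); n <- ncol(A)
  if (length(b) != m) stop("length(b) must equal nrow(A)")
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * norm(A, "F")

  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b)          # gradient of -f at x = 0
  iter <- 0L
  max_iter <- 3L * n + 30L

  while (iter < max_iter) {
    cand <- which(!passive & w > tol)
    if (length(cand) == 0L) break
    # largest dual, ties broken by lowest index (which.max takes the first)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    iter <- iter + 1L

    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0  # rank-deficient passive set: drop null directions
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  resid <- b - A %*% x
  structure(stats::setNames(as.vector(x), colnames(A)),
            residual_norm = sqrt(sum(resid^2)),
            iterations = iter)
}

#' Tikhonov-regularized non-negative least squares
#'
#' Minimizes `1/2 ||Ax - b||^2 + 1/2 lambda^2 ||x||^2` subject to `x >= 0`,
#' by augmenting `A` with `lambda * I` (n extra rows) and `b` with n zeros and
#' calling [solve_nnls()]. The ridge term stabilizes the solution when
#' reference genomes have nearly identical k-mer compositions (collinear
#' columns); `lambda = 0` reduces exactly to plain NNLS. The returned
#' `residual_norm` attribute is `||Ax - b||` of the *unaugmented* system.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param lambda non-negative regularization strength. The package default in
#'   the profiling pipeline is `1e-4`, small relative to the unit column
#'   norms of a reference matrix.
#' @inheritParams solve_nnls
#' @return as [solve_nnls()].
#' @export
solve_regularized <- function(A, b, lambda = 1e-4, tol = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single non-negative number")
  A <- as.matrix(A)
  if (lambda == 0) return(solve_nnls(A, b, tol = tol))
  n <- ncol(A)
  A_aug <- rbind(A, diag(lambda, n))
  b_aug <- c(b, numeric(n))
  x <- solve_nnls(A_aug, b_aug, tol = tol)
  resid <- b - A %*% as.vector(x)
  structure(stats::setNames(as.vector(x), colnames(A)),
            residual_norm = sqrt(sum(resid^2)),
            iterations = attr(x, "iterations"))
}

#' Verify the KKT optimality conditions of an NNLS solution
#'
#' Direct gradient check, independent of how `x` was obtained: with
#' `g = A'(Ax - b)`, optimality requires `|g| <= tol` wherever `x > 0` and
#' `g >= -tol` wherever `x = 0` (no descent direction into the feasible set).
#'
#' @param A,b the NNLS problem.
#' @param x candidate solution (non-negative).
#' @param tol tolerance (default 1e-6).
#' @return `TRUE`/`FALSE`, with attribute `max_violation`.
#' @export
kkt_check <- function(A, b, x, tol = 1e-6) {
  g <- as.vector(crossprod(A, A %*% x - b))
  pos <- x > tol
  viol <- max(c(0, abs(g[pos]), -g[!pos]))
  structure(viol <= tol, max_violation = viol)
}

#' Project a raw non-negative solution onto the probability simplex
#'
#' Divides by the sum so abundances are relative (sum to 1). A zero vector —
#' no genome explains any signal — stays zero and is flagged degenerate.
#'
#' @param raw non-negative numeric vector, optionally named by genome id.
#' @param lambda_used regularization strength recorded in the result.
#' @return an object of class `abundance_profile`: fields `genome_ids`,
#'   `abundances` (sum 1, or all zero), `residual_norm` (carried over from the
#'   solver if present), `lambda_used`, `degenerate`.
#' @export
normalize_to_simplex <- function(raw, lambda_used = NA_real_) {
  if (any(raw < 0)) stop("'raw' must be non-negative")
  s <- sum(raw)
  degenerate <- s <= 0
  ab <- if (degenerate) as.vector(raw) else as.vector(raw) / s
  structure(
    list(genome_ids = names(raw),
         abundances = unname(ab),
         residual_norm = attr(raw, "residual_norm") %||% NA_real_,
         lambda_used = lambda_used,
         degenerate = degenerate),
    class = "abundance_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop trace abundances and renormalize
#'
#' Entries below `min_abundance` are zeroed and the remainder rescaled to sum
#' to 1. A cutoff of 0 is the identity; a cutoff exceeding every entry yields
#' a degenerate all-zero profile.
#'
#' @param profile an `abundance_profile`.
#' @param min_abundance fraction in `[0, 1)`.
#' @return an `abundance_profile`.
#' @export
threshold_profile <- function(profile, min_abundance = 0) {
  stopifnot(inherits(profile, "abundance_profile"))
  if (min_abundance < 0 || min_abundance >= 1)
    stop("'min_abundance' must be in [0, 1)")
  if (min_abundance == 0) return(profile)
  ab <- profile$abundances
  ab[ab < min_abundance] <- 0
  s <- sum(ab)
  profile$degenerate <- s <= 0
  profile$abundances <- if (profile$degenerate) ab else ab / s
  profile
}

#' @export
print.abundance_profile <- function(x, n = 10L, ...) {
  cat(sprintf("abundance_profile: %d genomes%s, residual %.4g, lambda %.3g\n",
              length(x$abundances),
              if (x$degenerate) " [degenerate]" else "",
              x$residual_norm, x$lambda_used))
  ord <- order(-x$abundances)
  top <- utils::head(ord[x$abundances[ord] > 0], n)
  for (i in top)
    cat(sprintf("  %-30s %8.4f\n",
                x$genome_ids[i] %||% paste0("genome", i), x$abundances[i]))
  invisible(x)
}
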