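#' Soft-thresholding operator
#'
#' `sign(v) * pmax(|v| - lam, 0)`, the proximal operator of the L1 norm and
#' the inner operator of the penalized matrix decomposition.
#'
#' @param v numeric vector.
#' @param lam threshold, >= 0.
#' @return thresholded vector.
#' @export
soft_threshold <- function(v, lam) {
  stopifnot(lam >= 0)
  sign(v) * pmax(abs(v) - lam, 0)
}

# Unit-L2 vector proportional to soft_threshold(a, lam) with the smallest
# lam >= 0 giving L1 norm <= c (bisection); shared with the two-block solver
# through the compiled core.
l1_unit <- function(a, c1) {
  as.numeric(.l1_unit_cpp(a, c1))
}

#' Rank-one sparse CCA by penalized matrix decomposition
#'
#' Alternates L1-bounded unit-norm updates
#' `w_x <- normalize(soft_threshold(C w_y, lam_x))` (and symmetrically for
#' `w_y`) on the cross-covariance `C = X'Y / (n-1)`, where at each step the
#' threshold is chosen by bisection as the smallest value making
#' `||w||_1 <= s sqrt(p)` after L2 normalization.  The sparsity parameter `s`
#' follows the L1-bound convention `c = s * sqrt(p)`; `s = 1` removes the
#' constraint and the solution is the leading singular-vector pair of `C`.
#' Deterministic: initialized from the leading singular vectors of `C` unless
#' `init` is supplied.
#'
#' @param X,Y column-standardized matrices with equal row counts.
#' @param s_x,s_y sparsity parameters in `[1/sqrt(p), 1]` per view.
#' @param tol convergence tolerance on the max weight change.
#' @param max_iter maximum alternations.
#' @param init optional list `(wx, wy)` of starting vectors.
#' @return object of class `sparse_weights`: unit-L2 `wx`, `wy` (named by
#'   columns), objective `d = wx' C wy` (>= 0 by sign convention),
#'   `iterations`, `converged`, and the sparsity parameters.
#' @export
pmd_rank1 <- function(X, Y, s_x = 0.5, s_y = 0.5, tol = 1e-6,
                      max_iter = 200L, init = NULL) {
  X <- ft_values(X); Y <- ft_values(Y)
  stopifnot(nrow(X) == nrow(Y))
  p <- ncol(X); q <- ncol(Y)
  if (s_x < 1 / sqrt(p) - 1e-12 || s_x > 1 || s_y < 1 / sqrt(q) - 1e-12 || s_y > 1) {
    stop("sparsity must lie in [1/sqrt(p), 1]")
  }
  C <- crossprod(X, Y) / (nrow(X) - 1)
  if (all(abs(C) < 1e-14)) stop("no covariance signal: cross-covariance is zero")
  fit <- if (is.null(init)) {
    .pmd_rank1_cpp(C, s_x * sqrt(p), s_y * sqrt(q), tol, as.integer(max_iter))
  } else {
    .pmd_rank1_cpp(C, s_x * sqrt(p), s_y * sqrt(q), tol, as.integer(max_iter),
                   init$wx, init$wy)
  }
  structure(list(wx = setNames(as.numeric(fit$wx), colnames(X)),
                 wy = setNames(as.numeric(fit$wy), colnames(Y)),
                 d = fit$d, iterations = fit$iterations,
                 converged = fit$converged, sparsity_x = s_x, sparsity_y = s_y),
            class = "sparse_weights")
}

#' @export
print.sparse_weights <- function(x, ...) {
  cat(sprintf("sparse_weights: %d/%d non-zero (X), %d/%d non-zero (Y), d = %.4f, %s in %d iterations\n",
              sum(abs(x$wx) > 1e-8), length(x$wx),
              sum(abs(x$wy) > 1e-8), length(x$wy), x$d,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' First canonical pair without sparsity constraints
#'
#' Classical CCA via singular value decomposition of the whitened
#' cross-covariance `(S_xx + eps I)^(-1/2) S_xy (S_yy + eps I)^(-1/2)`; the
#' small ridge stabilizes near-collinear refit sets.  The canonical
#' correlation is the leading singular value clipped to `[0, 1]`; weights are
#' back-transformed, unit-L2-normalized, and the sign is fixed so the
#' correlation of the variates is non-negative.
#'
#' @param X,Y matrices with more rows than columns (apply stability selection
#'   first otherwise); columns are centered internally.
#' @param ridge_eps whitening ridge (default 1e-6).
#' @return object of class `cca_fit`: `wx`, `wy` (unit L2), `canonical_r`,
#'   `ridge_eps`.
#' @export
cca_unpenalized <- function(X, Y, ridge_eps = 1e-6) {
  X <- ft_values(X); Y <- ft_values(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) <= ncol(X) || nrow(Y) <= ncol(Y)) {
    stop("fewer rows than columns; run stability selection to reduce the feature set first")
  }
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  n <- nrow(Xc)
  Sxx <- crossprod(Xc) / (n - 1) + diag(ridge_eps, ncol(Xc))
  Syy <- crossprod(Yc) / (n - 1) + diag(ridge_eps, ncol(Yc))
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  isqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(e$values, 1e-12)
    e$vectors %*% (t(e$vectors) / sqrt(vals))
  }
  Wx <- isqrt(Sxx); Wy <- isqrt(Syy)
  K <- Wx %*% Sxy %*% Wy
  sv <- svd(K, nu = 1, nv = 1)
  wx <- as.numeric(Wx %*% sv$u[, 1])
  wy <- as.numeric(Wy %*% sv$v[, 1])
  wx <- wx / sqrt(sum(wx^2)); wy <- wy / sqrt(sum(wy^2))
  r <- min(max(sv$d[1], 0), 1)
  if (cor(Xc %*% wx, Yc %*% wy)[1] < 0) wy <- -wy
  structure(list(wx = setNames(wx, colnames(X)), wy = setNames(wy, colnames(Y)),
                 canonical_r = r, ridge_eps = ridge_eps), class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("cca_fit: canonical r = %.4f (p = %d, q = %d)\n",
              x$canonical_r, length(x$wx), length(x$wy)))
  invisible(x)
}

#' Projection deflation of an extracted component
#'
#' `M' = M (I - w w')`, so `M' w = 0` exactly: the component direction is
#' removed before searching for the next canonical mode.
#'
#' @param M numeric matrix.
#' @param w unit-L2 vector of length `ncol(M)`.
#' @return deflated matrix.
#' @export
projection_deflate <- function(M, w) {
  M <- ft_values(M)
  stopifnot(length(w) == ncol(M))
  if (abs(sqrt(sum(w^2)) - 1) > 1e-8) stop("w must have unit Euclidean norm")
  M - (M %*% w) %*% t(w)
}

#' Correlation of the canonical variates under fixed weights
#'
#' @param X,Y data matrices.
#' @param w_x,w_y weight vectors.
#' @return Pearson correlation of `X w_x` and `Y w_y`.
#' @export
canonical_correlation <- function(X, Y, w_x, w_y) {
  u <- as.numeric(ft_values(X) %*% w_x)
  v <- as.numeric(ft_values(Y) %*% w_y)
  if (sd(u) == 0 || sd(v) == 0) stop("zero-variance canonical variate")
  cor(u, v)
}
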