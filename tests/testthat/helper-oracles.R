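# Independent oracles used across the suite.  These deliberately take the
# "dumb but obviously correct" route and never share code with the package
# implementations they check.

# First canonical pair by the generalized-eigenvalue route:
# Sxx^-1 Sxy Syy^-1 Syx wx = r^2 wx.
cca_eigen_oracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  n <- nrow(Xc)
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  e <- eigen(M)
  r <- sqrt(max(Re(e$values)))
  wx <- Re(e$vectors[, which.max(Re(e$values))])
  wy <- as.numeric(solve(Syy) %*% t(Sxy) %*% wx)
  wx <- wx / sqrt(sum(wx^2))
  wy <- wy / sqrt(sum(wy^2))
  if (cor(Xc %*% wx, Yc %*% wy)[1] < 0) wy <- -wy
  list(r = r, wx = wx, wy = wy)
}

# Exhaustive check that a clumping result obeys the greedy contract: every
# retained index pair violates at least one gate, and every removed variant
# violates both gates against some earlier-promoted index.
clump_obeys_contract <- function(index_ids, gwas, g, r2 = 0.5, kb = 250) {
  D <- g$dosages
  pos <- setNames(gwas$pos, gwas$id)
  chrom <- setNames(gwas$chrom, gwas$id)
  pval <- setNames(gwas$p, gwas$id)
  linked <- function(a, b) {
    chrom[a] == chrom[b] && abs(pos[a] - pos[b]) <= kb * 1000 &&
      cor(D[, a], D[, b])^2 > r2
  }
  for (i in seq_along(index_ids)) {
    for (j in seq_len(i - 1)) {
      if (linked(index_ids[i], index_ids[j])) return(FALSE)
    }
  }
  removed <- setdiff(gwas$id, index_ids)
  for (v in removed) {
    earlier <- index_ids[pval[index_ids] < pval[v] |
                           (pval[index_ids] == pval[v] & pos[index_ids] <= pos[v])]
    if (!any(vapply(earlier, function(a) linked(a, v), logical(1)))) {
      return(FALSE)
    }
  }
  TRUE
}

# Two-view data with one planted sparse mode: supports load on a shared pair
# of latents with correlation r_latent (no reliability calibration — the raw
# construction the core solvers are probed with).
planted_pair <- function(n, p, q, support_x, support_y, r_latent,
                         share = 0.6, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  v <- r_latent * u + sqrt(1 - r_latent^2) * rnorm(n)
  X <- matrix(rnorm(n * p), n)
  Y <- matrix(rnorm(n * q), n)
  for (j in support_x) X[, j] <- sqrt(share) * u + sqrt(1 - share) * rnorm(n)
  for (j in support_y) Y[, j] <- sqrt(share) * v + sqrt(1 - share) * rnorm(n)
  colnames(X) <- paste0("x", seq_len(p))
  colnames(Y) <- paste0("y", seq_len(q))
  list(X = scale(X), Y = scale(Y))
}

# Small genotype set with chosen positions/r2 structure for clumping tests.
toy_genotypes <- function(dosages, pos, chrom = 1L, p = NULL) {
  m <- ncol(dosages)
  colnames(dosages) <- sprintf("v%02d", seq_len(m))
  info <- data.frame(id = colnames(dosages), chrom = chrom, pos = pos,
                     effect_allele = "A", other_allele = "G",
                     gene = "GENE1", maf = pmin(colMeans(dosages) / 2,
                                                1 - colMeans(dosages) / 2),
                     info = 1, stringsAsFactors = FALSE)
  structure(list(dosages = dosages, info = info), class = "genotype_matrix")
}
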