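#' Variant quality control
#'
#' Drops variants with minor allele frequency below `maf_min` or imputation
#' INFO score below `info_min`.
#'
#' @param g a `genotype_matrix` (see [simulate_genotypes()] /
#'   [read_dosages()]).
#' @param maf_min minimum MAF (default 0.001).
#' @param info_min minimum INFO (default 0.3).
#' @return the filtered `genotype_matrix` with attribute `n_dropped`.
#' @export
qc_variants <- function(g, maf_min = 0.001, info_min = 0.3) {
  keep <- g$info$maf >= maf_min & g$info$info >= info_min
  out <- structure(list(dosages = g$dosages[, keep, drop = FALSE],
                        info = g$info[keep, , drop = FALSE]),
                   class = "genotype_matrix")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Additive-dosage association scan
#'
#' Per variant, ordinary least squares of the phenotype on
#' `[1, dosage, covariates]`; reports the dosage coefficient, its standard
#' error, t statistic and two-sided p value (t distribution, `n - k` residual
#' degrees of freedom).  Implemented by Frisch-Waugh-Lovell: phenotype and
#' dosages are residualized on the covariate design once, which is exactly
#' equivalent to the full per-variant regression.
#'
#' @param y numeric phenotype vector (e.g. a canonical symptom variate),
#'   aligned with the genotype rows.
#' @param g a `genotype_matrix`.
#' @param covariates optional matrix or [feature_table] of covariates
#'   (complete cases required).
#' @return data frame of class `gwas_table`: id, chrom, pos, effect_allele,
#'   other_allele, beta, se, t, p, n_used.
#' @export
gwas_linear <- function(y, g, covariates = NULL) {
  D <- g$dosages
  n <- nrow(D)
  stopifnot(length(y) == n)
  Z <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind(`(Intercept)` = 1, ft_values(covariates))
  }
  keep <- complete.cases(Z) & !is.na(y)
  y <- y[keep]; Z <- Z[keep, , drop = FALSE]; D <- D[keep, , drop = FALSE]
  n <- length(y)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    bad <- colnames(Z)[qrZ$pivot[(qrZ$rank + 1):ncol(Z)]]
    stop("collinear covariates: ", paste(bad, collapse = ", "))
  }
  ry <- qr.resid(qrZ, y)
  rD <- qr.resid(qrZ, D)
  df <- n - ncol(Z) - 1
  ss_d <- colSums(rD^2)
  if (any(ss_d < 1e-12)) {
    stop("zero-variance dosage after covariate adjustment: ",
         paste(g$info$id[ss_d < 1e-12], collapse = ", "))
  }
  beta <- colSums(rD * ry) / ss_d
  rss <- sum(ry^2) - beta^2 * ss_d
  se <- sqrt(rss / df / ss_d)
  t <- beta / se
  p <- 2 * pt(-abs(t), df)
  out <- data.frame(id = g$info$id, chrom = g$info$chrom, pos = g$info$pos,
                    effect_allele = g$info$effect_allele,
                    other_allele = g$info$other_allele,
                    beta = beta, se = se, t = t, p = p, n_used = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gwas_table", "data.frame")
  out
}

#' Bonferroni significance threshold over variants and symptom groups
#'
#' `alpha = 0.05 / (n_variants * n_groups)`.
#'
#' @param n_variants number of tested variants.
#' @param n_groups number of significant symptom groups scanned.
#' @param alpha family-wise level (default 0.05).
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(n_variants, n_groups = 1, alpha = 0.05) {
  stopifnot(n_variants >= 1, n_groups >= 1)
  alpha / (n_variants * n_groups)
}

#' Squared dosage correlation between two variants
#'
#' @param g a `genotype_matrix`.
#' @param i,j variant ids or column indices.
#' @return squared Pearson correlation of the dosage columns.
#' @export
ld_r2 <- function(g, i, j) {
  di <- g$dosages[, i]
  dj <- g$dosages[, j]
  if (sd(di) == 0 || sd(dj) == 0) stop("zero-variance dosage")
  cor(di, dj)^2
}

#' Greedy LD clumping of an association scan
#'
#' Variants are sorted by ascending p value (ties broken by position, then
#' id); the best unassigned variant becomes an index, and all unassigned
#' variants on the same chromosome within `kb` kilobases (boundary inclusive)
#' AND with dosage `r^2 > r2` against the index are assigned to its clump.
#' Repeats until no variant is unassigned.  Variants with `p > p1` are never
#' promoted to index (`p1 = 1` admits all, the default).
#'
#' @param gwas a `gwas_table`.
#' @param g the aligned `genotype_matrix`.
#' @param p1 index-variant p-value ceiling (default 1).
#' @param r2 clumping r-squared gate (default 0.5).
#' @param kb clumping window in kb (default 250).
#' @return character vector of index variant ids (in promotion order).
#' @export
clump <- function(gwas, g, p1 = 1.0, r2 = 0.5, kb = 250) {
  stopifnot(all(gwas$id == g$info$id))
  ord <- order(gwas$p, gwas$pos, gwas$id)
  assigned <- rep(FALSE, nrow(gwas))
  index <- character(0)
  D <- g$dosages
  for (o in ord) {
    if (assigned[o]) next
    if (gwas$p[o] > p1) { assigned[o] <- TRUE; next }
    index <- c(index, gwas$id[o])
    assigned[o] <- TRUE
    near <- !assigned & gwas$chrom == gwas$chrom[o] &
      abs(gwas$pos - gwas$pos[o]) <= kb * 1000
    for (j in which(near)) {
      if (cor(D[, o], D[, j])^2 > r2) assigned[j] <- TRUE
    }
  }
  index
}

#' Weighted allele scores per gene
#'
#' `score[participant, gene] = sum over the gene's index variants of
#' (effect-allele dosage x GWAS beta)`.
#'
#' @param g a `genotype_matrix`.
#' @param gwas the `gwas_table` supplying the betas.
#' @param index_variants ids retained by [clump()].
#' @param gene_map optional named vector mapping variant id to gene; defaults
#'   to the `gene` column of `g$info`.
#' @return list: `scores` (participants x genes matrix), `variants`
#'   (per-gene data frame of index variants and betas), `genes_without_index`.
#' @export
gene_score <- function(g, gwas, index_variants, gene_map = NULL) {
  if (is.null(gene_map)) {
    gene_map <- setNames(g$info$gene, g$info$id)
  }
  beta <- setNames(gwas$beta, gwas$id)
  idx <- intersect(index_variants, colnames(g$dosages))
  genes_all <- unique(gene_map[colnames(g$dosages)])
  by_gene <- split(idx, gene_map[idx])
  scores <- if (length(by_gene) == 0) {
    matrix(0, nrow(g$dosages), 0, dimnames = list(rownames(g$dosages), NULL))
  } else {
    matrix(sapply(by_gene, function(vs) {
      g$dosages[, vs, drop = FALSE] %*% beta[vs]
    }), nrow = nrow(g$dosages),
    dimnames = list(rownames(g$dosages), names(by_gene)))
  }
  variants <- do.call(rbind, lapply(names(by_gene), function(gn) {
    data.frame(gene = gn, id = by_gene[[gn]],
               beta = unname(beta[by_gene[[gn]]]), stringsAsFactors = FALSE)
  }))
  list(scores = scores, variants = variants,
       genes_without_index = setdiff(genes_all, names(by_gene)))
}

#' Compare an exposure-symptom correlation between gene-score strata
#'
#' Splits participants into low and high strata at the score median (default)
#' or tertile boundaries, computes the Pearson correlation of the exposure
#' profile with the symptom group in each stratum, and tests the difference
#' with Fisher's z:
#' `z = (atanh r_low - atanh r_high) / sqrt(1/(n_low - 3) + 1/(n_high - 3))`,
#' two-sided normal p value.
#'
#' @param profile exposure (environmental profile) vector.
#' @param symptoms symptom-group vector.
#' @param score gene-score vector.
#' @param split `"median"` or `"tertile"` (outer tertiles compared).
#' @return list: `r_low`, `r_high`, `n_low`, `n_high`, `z`, `p`.
#' @export
stratified_correlation_test <- function(profile, symptoms, score,
                                        split = c("median", "tertile")) {
  split <- match.arg(split)
  stopifnot(length(profile) == length(symptoms),
            length(profile) == length(score))
  if (split == "median") {
    cut_lo <- score <= median(score)
    cut_hi <- !cut_lo
  } else {
    qs <- quantile(score, c(1 / 3, 2 / 3))
    cut_lo <- score <= qs[1]
    cut_hi <- score > qs[2]
  }
  n_low <- sum(cut_lo); n_high <- sum(cut_hi)
  if (n_low < 10 || n_high < 10) stop("stratum too small (n < 10)")
  r_low <- cor(profile[cut_lo], symptoms[cut_lo])
  r_high <- cor(profile[cut_hi], symptoms[cut_hi])
  z <- (atanh(r_low) - atanh(r_high)) /
    sqrt(1 / (n_low - 3) + 1 / (n_high - 3))
  list(r_low = r_low, r_high = r_high, n_low = n_low, n_high = n_high,
       z = z, p = 2 * pnorm(-abs(z)))
}
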