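test_that("variant QC drops exactly the failing variants", {
  set.seed(1)
  dos <- matrix(rbinom(50 * 10, 2, 0.3), 50,
                dimnames = list(sprintf("P%02d", 1:50), sprintf("v%02d", 1:10)))
  g <- toy_genotypes(dos, pos = (1:10) * 1000)
  g$info$maf <- c(0.0005, rep(0.25, 9))
  g$info$info <- c(1, 1, 0.2, 0.1, rep(1, 6))
  out <- qc_variants(g)
  expect_equal(ncol(out$dosages), 7)
  expect_equal(attr(out, "n_dropped"), 3L)
  expect_false("v01" %in% out$info$id)
  expect_false("v03" %in% out$info$id)

  g$info$maf <- rep(0.25, 10); g$info$info <- rep(1, 10)
  expect_equal(ncol(qc_variants(g)$dosages), 10)
})

test_that("per-variant association equals the reference least-squares solve", {
  set.seed(2)
  n <- 400
  dos <- matrix(rbinom(n * 20, 2, runif(20, 0.1, 0.5)), n, byrow = TRUE)
  dos <- matrix(rbinom(n * 20, 2, 0.3), n)
  rownames(dos) <- sprintf("P%03d", 1:n)
  g <- toy_genotypes(dos, pos = (1:20) * 1e4)
  cov <- cbind(age = rnorm(n, 50, 5), sex = rbinom(n, 1, 0.5))
  rownames(cov) <- rownames(dos)
  y <- 0.1 * dos[, 3] + 0.02 * cov[, "age"] + rnorm(n)
  res <- gwas_linear(y, g, cov)
  for (j in c(1, 3, 7, 20)) {
    ref <- summary(lm(y ~ dos[, j] + cov))$coefficients[2, ]
    expect_equal(res$beta[j], unname(ref["Estimate"]), tolerance = 1e-8)
    expect_equal(res$se[j], unname(ref["Std. Error"]), tolerance = 1e-8)
    expect_equal(res$p[j], unname(ref["Pr(>|t|)"]), tolerance = 1e-8)
  }
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$se > 0))
})

test_that("association scan recovers a planted dosage effect", {
  set.seed(3)
  n <- 20000
  dos <- matrix(rbinom(n * 5, 2, 0.3), n)
  rownames(dos) <- sprintf("P%05d", 1:n)
  g <- toy_genotypes(dos, pos = (1:5) * 1e4)
  y <- 0.2 * dos[, 2] + rnorm(n)
  res <- gwas_linear(y, g)
  expect_gt(res$beta[2], 0.18)
  expect_lt(res$beta[2], 0.22)
  expect_lt(res$p[2], 1e-10)
})

test_that("Bonferroni threshold follows the stated rule", {
  expect_equal(bonferroni_threshold(100, 1), 5e-4)
  expect_equal(bonferroni_threshold(1, 1), 0.05)
  expect_equal(bonferroni_threshold(13918727, 3), 0.05 / 41756181,
               tolerance = 1e-12)
})

test_that("dosage r2 behaves at its boundaries", {
  set.seed(4)
  dos <- matrix(rbinom(200 * 3, 2, 0.4), 200)
  dos <- cbind(dos, dos[, 1])
  rownames(dos) <- sprintf("P%03d", 1:200)
  g <- toy_genotypes(dos, pos = (1:4) * 1000)
  expect_equal(ld_r2(g, 1, 1), 1)
  expect_equal(ld_r2(g, 1, 4), 1)
  expect_lt(ld_r2(g, 1, 2), 0.1)
  g$dosages[, 2] <- 1
  expect_error(ld_r2(g, 1, 2), "zero-variance")
})

test_that("clumping keeps the best of co-located correlated variants", {
  set.seed(5)
  n <- 500
  base <- rbinom(n, 2, 0.4)
  flip <- function(x) { i <- sample(n, 25); x[i] <- rbinom(25, 2, 0.4); x }
  dos <- cbind(base, flip(base), flip(base))
  rownames(dos) <- sprintf("P%03d", 1:n)
  g <- toy_genotypes(dos, pos = c(1000, 2000, 3000))
  gw <- data.frame(id = g$info$id, chrom = 1L, pos = g$info$pos,
                   p = c(0.2, 0.01, 0.4))
  idx <- clump(gw, g)
  expect_identical(idx, "v02")

  # distance gate: same r2 but 300 kb apart keeps both
  g2 <- toy_genotypes(dos[, 1:2], pos = c(1000, 301001))
  gw2 <- data.frame(id = g2$info$id, chrom = 1L, pos = g2$info$pos,
                    p = c(0.2, 0.01))
  expect_length(clump(gw2, g2), 2)
})

test_that("greedy clumping satisfies the exhaustive pairwise contract", {
  for (trial in 1:100) {
    set.seed(trial)
    n <- 200
    m <- sample(5:20, 1)
    base <- matrix(rbinom(n * m, 2, 0.4), n)
    # random LD: some columns are noisy copies of earlier ones
    for (j in seq_len(m)) {
      if (j > 1 && runif(1) < 0.4) {
        src <- sample(j - 1, 1)
        base[, j] <- base[, src]
        i <- sample(n, 40)
        base[i, j] <- rbinom(40, 2, 0.4)
      }
    }
    rownames(base) <- sprintf("P%03d", 1:n)
    pos <- sort(sample(1:5e5, m))
    g <- toy_genotypes(base, pos = pos)
    gw <- data.frame(id = g$info$id, chrom = 1L, pos = pos,
                     p = runif(m))
    idx <- clump(gw, g, r2 = 0.5, kb = 250)
    expect_true(clump_obeys_contract(idx, gw, g, r2 = 0.5, kb = 250))
  }
})

test_that("gene scores are dosage-times-beta sums and linear in beta", {
  dos <- matrix(c(2, 1,
                  0, 1,
                  1, 2), 3, byrow = TRUE,
                dimnames = list(paste0("P", 1:3), c("v01", "v02")))
  g <- toy_genotypes(dos, pos = c(1000, 2000))
  g$info$gene <- c("GENEA", "GENEA")
  gw <- data.frame(id = c("v01", "v02"), beta = c(0.5, -0.2))
  gs <- gene_score(g, gw, index_variants = c("v01", "v02"))
  expect_equal(unname(gs$scores[, "GENEA"]), c(0.8, -0.2, 0.1))
  gw2 <- gw; gw2$beta <- 2 * gw$beta
  gs2 <- gene_score(g, gw2, index_variants = c("v01", "v02"))
  expect_equal(gs2$scores, 2 * gs$scores)

  gs0 <- gene_score(g, gw, index_variants = character(0))
  expect_equal(ncol(gs0$scores), 0)
  expect_true("GENEA" %in% gs0$genes_without_index)
})

test_that("the stratified Fisher z statistic matches its hand evaluation", {
  # analytic check on correlations 0.1 vs 0.5 with 50 per stratum
  z_hand <- (atanh(0.1) - atanh(0.5)) / sqrt(2 / 47)
  expect_equal(z_hand, -2.18, tolerance = 0.005)

  # identical strata: z = 0, p = 1 (construct mirrored strata)
  set.seed(6)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  profile <- c(x, x); symptoms <- c(y, y)
  score <- rep(c(0, 1), each = 50)
  out <- stratified_correlation_test(profile, symptoms, score)
  expect_equal(out$z, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)
  expect_error(stratified_correlation_test(x[1:12], y[1:12], rep(0:1, 6)),
               "stratum")
})

test_that("planted a-path moderation yields a significant stratified contrast", {
  set.seed(7)
  n <- 20000
  w <- rnorm(n)
  x <- rnorm(n)
  y <- (0.2 + 0.1 * w) * x + rnorm(n)
  out <- stratified_correlation_test(x, y, w)
  expect_lt(out$z, -3)
  expect_lt(out$p, 0.01)
  expect_lt(out$r_low, out$r_high)
})
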