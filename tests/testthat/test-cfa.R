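# Generate one-factor indicator data with loading lambda on a standard-normal
# latent; uniqueness 1 - lambda^2 so items have unit variance.
one_factor_data <- function(n, lambda, seed = 1) {
  set.seed(seed)
  p <- length(lambda)
  f <- rnorm(n)
  x <- sapply(seq_len(p), function(j) {
    lambda[j] * f + sqrt(1 - lambda[j]^2) * rnorm(n)
  })
  colnames(x) <- paste0("item", seq_len(p))
  list(x = x, f = f)
}

test_that("one-factor ML recovery of generating loadings", {
  d <- one_factor_data(20000, rep(0.7, 5), seed = 11)
  fit <- fit_cfa_one_factor(d$x)
  expect_true(fit$converged)
  expect_true(all(abs(fit$loadings - 0.7) < 0.05))
  expect_true(all(abs(fit$uniquenesses - 0.51) < 0.05))
  expect_gt(fit$fit$cfi, 0.99)
  expect_lt(fit$fit$rmsea, 0.02)
})

test_that("an exactly model-implied covariance gives zero discrepancy", {
  lambda <- c(0.8, 0.7, 0.6, 0.5, 0.4)
  psi <- 1 - lambda^2
  S <- tcrossprod(lambda) + diag(psi)
  fit <- stabcca:::cfa_fit_cov(S, n = 1000)
  expect_lt(fit$fml, 1e-8)
  expect_lt(fit$chi2, 1e-4)
  expect_equal(fit$loadings, lambda, tolerance = 1e-3)
})

test_that("independent items leave no common variance to explain", {
  # the one-factor model is unidentified at independence (a single-item
  # loading with matching uniqueness also reproduces a diagonal covariance),
  # so assert the identifiable content: implied cross-covariances vanish and
  # the fit is as good as the saturated/baseline comparison allows
  set.seed(3)
  x <- matrix(rnorm(20000 * 4), ncol = 4,
              dimnames = list(NULL, paste0("i", 1:4)))
  fit <- fit_cfa_one_factor(x)
  off <- fit$Sigma[lower.tri(fit$Sigma)]
  expect_lt(max(abs(off)), 0.03)
  expect_lt(fit$fit$srmr, 0.02)
  expect_lt(fit$chi2, fit$fit$chi2_baseline + 1e-8)
})

test_that("fit indices follow their formulas on hand-computed values", {
  fake <- list(chi2 = 100, df = 5, Sigma = diag(3))
  idx <- cfa_fit_indices(fake, S = diag(3), n = 1001,
                         chi2_baseline = 1000, df_baseline = 10)
  expect_equal(idx$cfi, 1 - 95 / 990, tolerance = 1e-12)
  expect_equal(idx$rmsea, sqrt(95 / 5000), tolerance = 1e-12)
  expect_equal(idx$tli, (100 - 20) / 99, tolerance = 1e-12)
  expect_equal(idx$srmr, 0)

  # chi2 = df forces RMSEA 0; perfect fit forces CFI 1
  idx2 <- cfa_fit_indices(list(chi2 = 5, df = 5, Sigma = diag(3)),
                          S = diag(3), n = 100, chi2_baseline = 50,
                          df_baseline = 3)
  expect_equal(idx2$rmsea, 0)
  idx3 <- cfa_fit_indices(list(chi2 = 0, df = 5, Sigma = diag(3)),
                          S = diag(3), n = 100, chi2_baseline = 50,
                          df_baseline = 3)
  expect_equal(idx3$cfi, 1)
  expect_error(cfa_fit_indices(list(chi2 = 1, df = 0, Sigma = diag(3)),
                               diag(3), 100), "df = 0")
})

test_that("estimates and fit indices match the factanal reference", {
  # factanal is an independent ML optimizer of the same discrepancy on the
  # correlation matrix; indices recomputed from its solution must agree.
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    lambda <- runif(6, 0.4, 0.85)
    d <- one_factor_data(3000, lambda, seed = seed + 100)
    z <- scale(d$x)
    fit <- fit_cfa_one_factor(z)
    ref <- factanal(covmat = cov(z), factors = 1, n.obs = nrow(z))
    lam_ref <- as.numeric(ref$loadings)
    if (sum(lam_ref) < 0) lam_ref <- -lam_ref
    worst <- max(worst, max(abs(fit$loadings - lam_ref)))
    ref_model <- list(chi2 = (nrow(z) - 1) * ref$criteria[["objective"]],
                      df = fit$df,
                      Sigma = tcrossprod(lam_ref) + diag(ref$uniquenesses))
    ref_idx <- cfa_fit_indices(ref_model, cov(z), nrow(z))
    expect_equal(fit$fit$cfi, ref_idx$cfi, tolerance = 1e-4)
    expect_equal(fit$fit$tli, ref_idx$tli, tolerance = 1e-4)
    expect_equal(fit$fit$rmsea, ref_idx$rmsea, tolerance = 1e-4)
    expect_equal(fit$fit$srmr, ref_idx$srmr, tolerance = 1e-4)
  }
  expect_lt(worst, 1e-3)
})

test_that("pruning removes exactly an appended misfitting noisy item", {
  # a noisy item with a residual dependence on one indicator breaks the
  # one-factor structure (a pure-noise item would not: its zero loading fits
  # perfectly); pruning must drop exactly that item and then stop
  d <- one_factor_data(20000, rep(0.7, 5), seed = 21)
  set.seed(22)
  shared <- rnorm(20000)
  x <- d$x
  x[, 5] <- x[, 5] + 0.6 * shared
  x <- cbind(x, noise = 0.7 * shared + 0.7 * rnorm(20000))
  model <- cfa_item_prune(x)
  trail <- attr(model, "trail")
  expect_setequal(names(model$loadings), colnames(d$x))
  expect_equal(trail$dropped[1], "noise")
  expect_equal(nrow(trail), 2)

  # already-excellent data: nothing removed
  m0 <- cfa_item_prune(d$x)
  expect_equal(nrow(attr(m0, "trail")), 1)
})

test_that("pruning at min_items raises a typed error carrying the trail", {
  set.seed(5)
  n <- 2000
  x <- cbind(i1 = rnorm(n), i2 = rnorm(n), i3 = rnorm(n))
  # p = 3 is just-identified (df = 0): indices undefined, criteria unmeetable
  expect_error(cfa_item_prune(x, min_items = 3), class = "stabcca_prune_error")
  err <- tryCatch(cfa_item_prune(x, min_items = 3),
                  stabcca_prune_error = function(e) e)
  expect_equal(nrow(err$trail), 1)
})

test_that("factor scores are deterministic, centered and recover the latent", {
  # 6 items at lambda 0.8: analytic score-latent correlation
  # sqrt(S/(1+S)) = 0.956 with S = 6 * 0.64/0.36
  d <- one_factor_data(20000, rep(0.8, 6), seed = 31)
  fit <- fit_cfa_one_factor(d$x)
  sc <- cfa_scores(fit, d$x)
  expect_gt(cor(sc, d$f), 0.95)
  zero_row <- matrix(fit$means, 1, dimnames = list(NULL, fit$item_names))
  expect_equal(cfa_scores(fit, zero_row), 0, tolerance = 1e-12)
  expect_error(cfa_scores(fit, d$x[, 1:3]), "lack")
})

test_that("build_categories copies single items and scores latents out of fold", {
  d <- one_factor_data(20000, c(0.8, 0.75, 0.7, 0.65, 0.6), seed = 41)
  extra <- rnorm(20000)
  x <- cbind(d$x, solo_item1 = extra)
  rownames(x) <- sprintf("P%05d", seq_len(nrow(x)))
  specs <- list(list(category_name = "latent_cat",
                     member_item_names = colnames(d$x)),
                list(category_name = "solo",
                     member_item_names = "solo_item1"))
  out <- build_categories(x, specs, n_folds = 5, seed = 2)
  expect_equal(colnames(out$values), c("latent_cat", "solo"))
  expect_equal(unname(out$values[, "solo"]), extra)
  expect_gt(cor(out$values[, "latent_cat"], d$f), 0.9)
  expect_false(anyNA(out$values))

  specs_bad <- list(list(category_name = "a", member_item_names = "item1"))
  expect_error(build_categories(x, specs_bad), "partition")
})
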