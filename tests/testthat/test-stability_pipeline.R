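# A compact planted dataset reused across the pipeline tests.
small_planted <- function(n = 2000, seed = 1) {
  planted_pair(n, p = 20, q = 12, support_x = 1:5, support_y = 1:4,
               r_latent = 0.45, seed = seed)
}

test_that("train/test split is disjoint, exhaustive and reproducible", {
  ids <- sprintf("P%03d", 1:100)
  sp <- split_train_test(ids, 0.9, seed = 4)
  expect_length(sp$train_ids, 90)
  expect_length(sp$test_ids, 10)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  sp2 <- split_train_test(ids, 0.9, seed = 4)
  expect_identical(sp, sp2)
})

test_that("stability selection keeps a planted support and little else", {
  dat <- small_planted(seed = 11)
  cfg <- pipeline_config(n_resamples = 50, seed = 2)
  ss <- stability_select(dat$X, dat$Y, cfg)
  expect_true(all(paste0("x", 1:5) %in% ss$stable_x))
  expect_true(all(paste0("y", 1:4) %in% ss$stable_y))
  false_rate <- mean(ss$freq_x[paste0("x", 6:20)] >= cfg$stability_threshold)
  expect_lte(false_rate, 0.2)
  expect_false(ss$no_signal)
})

test_that("a zero threshold makes every feature stable", {
  dat <- small_planted(n = 300, seed = 3)
  cfg <- pipeline_config(n_resamples = 10, stability_threshold = 0,
                         seed = 1)
  ss <- stability_select(dat$X, dat$Y, cfg)
  expect_length(ss$stable_x, 20)
  expect_length(ss$stable_y, 12)
})

test_that("pure-noise views report no stable signal", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    X <- scale(matrix(rnorm(600 * 15), 600))
    Y <- scale(matrix(rnorm(600 * 8), 600))
    colnames(X) <- paste0("x", 1:15); colnames(Y) <- paste0("y", 1:8)
    cfg <- pipeline_config(n_resamples = 40, seed = seed)
    if (stability_select(X, Y, cfg)$no_signal) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("the train permutation p value hits its formula-forced floor", {
  dat <- small_planted(seed = 21)
  cfg <- pipeline_config(n_resamples = 30, n_perm = 19, seed = 5)
  ss <- stability_select(dat$X, dat$Y, cfg)
  rf <- stabcca:::refit_stable(dat$X, dat$Y, ss$stable_x, ss$stable_y)
  pt <- permutation_test_train(dat$X, dat$Y, cfg, rf$r_train, seed = 6)
  expect_equal(pt$p_perm, 1 / 20)           # observed beats all 19 permutations
  expect_length(pt$r_perm, 19)
  # a degenerate observed value can never be beaten
  pt0 <- permutation_test_train(dat$X, dat$Y, cfg, r_obs = -1, seed = 6)
  expect_equal(pt0$p_perm, 1)
})

test_that("test-set evaluation keeps weights fixed and honours n_perm = 0", {
  dat <- small_planted(n = 3000, seed = 31)
  tr <- 1:2500; te <- 2501:3000
  cfg <- pipeline_config(n_resamples = 40, seed = 7)
  ss <- stability_select(dat$X[tr, ], dat$Y[tr, ], cfg)
  rf <- stabcca:::refit_stable(dat$X[tr, ], dat$Y[tr, ], ss$stable_x, ss$stable_y)
  ev <- evaluate_test(list(wx = rf$wx, wy = rf$wy),
                      dat$X[te, ], dat$Y[te, ], n_perm = 99, seed = 8)
  expect_gt(ev$r_test, 0.2)
  expect_equal(ev$p_perm_test, 1 / 100)
  ev0 <- evaluate_test(list(wx = rf$wx, wy = rf$wy),
                       dat$X[te, ], dat$Y[te, ], n_perm = 0)
  expect_true(is.na(ev0$p_perm_test))
  expect_error(evaluate_test(list(wx = rf$wx[-1], wy = rf$wy),
                             dat$X[te, ], dat$Y[te, ], 0),
               "mismatch")
})

test_that("run_multi_mode respects max_modes and returns orthogonal variates", {
  dat <- small_planted(n = 2500, seed = 41)
  cfg1 <- pipeline_config(n_resamples = 30, n_perm = 49, max_modes = 1,
                          seed = 9)
  res1 <- run_multi_mode(dat$X, dat$Y, cfg1)
  expect_length(res1$modes, 1)

  cfg <- pipeline_config(n_resamples = 30, n_perm = 49, max_modes = 3,
                         seed = 9)
  res <- run_multi_mode(dat$X, dat$Y, cfg)
  if (length(res$modes) >= 2) {
    v1 <- res$modes[[1]]$variate_x_train
    v2 <- res$modes[[2]]$variate_x_train
    expect_lt(abs(cor(v1, v2)), 1e-6)
  }
  expect_gte(res$n_significant, 1)
  # determinism of the full orchestration
  res_b <- run_multi_mode(dat$X, dat$Y, cfg)
  expect_equal(res$modes[[1]]$r_test, res_b$modes[[1]]$r_test)
  expect_identical(res$modes[[1]]$stable_x, res_b$modes[[1]]$stable_x)
})

test_that("cross-loading FEV normalizes to 100 per symptom group", {
  set.seed(51)
  n <- 1000
  X <- scale(matrix(rnorm(n * 10), n))
  colnames(X) <- paste0("x", 1:10)
  v <- cbind(X[, 1] + rnorm(n), X[, 6] + rnorm(n))
  sets <- list(paste0("x", 1:3), paste0("x", 6:8))
  out <- crossloadings_ev_fev(X, v, sets)
  expect_equal(unname(colSums(out$fev)), c(100, 100), tolerance = 1e-8)
  expect_gt(out$fev[1, 1], 50)   # profile 1 dominates its own group
  expect_gt(out$fev[2, 2], 50)
  expect_equal(dim(out$ev), c(10, 2))

  # single mode: trivially 100%
  out1 <- crossloadings_ev_fev(X, v[, 1, drop = FALSE], sets[1])
  expect_equal(unname(out1$fev[1, 1]), 100)
})

test_that("reliability checks reproduce the fitted mode under resampling", {
  dat <- small_planted(n = 3000, seed = 61)
  cfg <- pipeline_config(n_resamples = 30, n_perm = 19, max_modes = 1,
                         seed = 13)
  res <- run_multi_mode(dat$X, dat$Y, cfg)
  set.seed(62)
  sex <- rbinom(3000, 1, 0.5)
  rel <- reliability_suite(dat$X, dat$Y, cfg, res, sex = sex,
                           fractions = c(0.1, 0.5, 1.0, 1.5), n_rep = 10,
                           seed = 14)
  sw <- rel$subsample_sweep
  full_r <- sw$r_mean[sw$fraction == 1.0]
  boot_r <- sw$r_mean[sw$fraction == 1.5]
  expect_lt(abs(boot_r - res$modes[[1]]$r_train), 0.05)
  # smaller subsamples fluctuate more
  expect_gt(sw$r_sd[sw$fraction == 0.1], sw$r_sd[sw$fraction == 1.5])
  expect_gt(mean(rel$bootstrap_loadings), 0.9)
  expect_lt(abs(diff(rel$sex_split$r_by_sex)), 0.1)
})
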