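#' Configuration of the stability-selected sparse CCA pipeline
#'
#' Defaults follow the reference protocol: a 90/10 train-test split, 100
#' half-sample resamples, a 90% non-zero-frequency stability threshold,
#' sparsity 0.5 per view, 1,000 permutations, and BH-FDR at 0.05 across modes.
#'
#' @param n_resamples number of stability-selection resamples.
#' @param resample_fraction fraction of the training sample per resample
#'   (drawn without replacement; default 0.5).
#' @param stability_threshold minimum non-zero selection frequency `tau`.
#' @param sparsity L1-bound sparsity parameter `s` per view.
#' @param n_perm number of permutations for train and test inference.
#' @param train_fraction fraction of participants used for training.
#' @param alpha_fdr significance level for the FDR-corrected test p-values.
#' @param max_modes maximum number of canonical modes to extract.
#' @param ridge_eps whitening ridge of the unpenalized refit.
#' @param seed integer seed governing the split, resamples and permutations.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_resamples = 100L, resample_fraction = 0.5,
                            stability_threshold = 0.9, sparsity = 0.5,
                            n_perm = 1000L, train_fraction = 0.9,
                            alpha_fdr = 0.05, max_modes = 5L,
                            ridge_eps = 1e-6, seed = 1L) {
  stopifnot(stability_threshold >= 0, stability_threshold <= 1,
            train_fraction > 0, train_fraction < 1,
            resample_fraction > 0, resample_fraction <= 1,
            n_resamples >= 1, max_modes >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Reproducible train/test participant split
#'
#' @param ids participant identifiers.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @return list `train_ids`, `test_ids` (disjoint, exhaustive).
#' @export
split_train_test <- function(ids, train_fraction = 0.9, seed = 1L) {
  n <- length(ids)
  stopifnot(n >= 10, train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  n_train <- round(n * train_fraction)
  train <- sort(sample.int(n, n_train))
  list(train_ids = ids[train], test_ids = ids[-train])
}

#' Stability selection of sparse CCA supports under half-sample resampling
#'
#' Runs the rank-one penalized matrix decomposition on `n_resamples`
#' subsamples of `resample_fraction * n` participants (without replacement
#' within a resample) and retains, per view, the features whose weight is
#' non-zero in at least `stability_threshold` of the resamples.
#'
#' @param X,Y preprocessed (residualized, standardized) matrices.
#' @param config a [pipeline_config()].
#' @param seed seed for the resample draws (default `config$seed`).
#' @return list: `freq_x`, `freq_y` (named selection frequencies), `stable_x`,
#'   `stable_y` (feature names), `no_signal` flag (`TRUE` when either stable
#'   set is empty — a typed outcome, not an error).
#' @export
stability_select <- function(X, Y, config, seed = config$seed) {
  X <- ft_values(X); Y <- ft_values(Y)
  n <- nrow(X)
  m <- max(2L, floor(config$resample_fraction * n))
  set.seed(seed)
  idx <- vapply(seq_len(config$n_resamples),
                function(i) sample.int(n, m), integer(m))
  ## looser inner tolerance than the exported solver: only the non-zero
  ## pattern matters here and it stabilizes within a few dozen sweeps
  fr <- .stability_freq_cpp(X, Y, idx - 1L,
                            config$sparsity * sqrt(ncol(X)),
                            config$sparsity * sqrt(ncol(Y)),
                            1e-5, 60L)
  freq_x <- setNames(as.numeric(fr$freq_x), colnames(X))
  freq_y <- setNames(as.numeric(fr$freq_y), colnames(Y))
  stable_x <- names(freq_x)[freq_x >= config$stability_threshold]
  stable_y <- names(freq_y)[freq_y >= config$stability_threshold]
  list(freq_x = freq_x, freq_y = freq_y,
       stable_x = stable_x, stable_y = stable_y,
       no_signal = length(stable_x) == 0 || length(stable_y) == 0)
}

# Residualize the columns of M on an extracted variate u (row-space part of
# the orthogonalized deflation).
resid_on_variate <- function(M, u) {
  u <- as.numeric(u)
  ss <- sum(u^2)
  if (ss < 1e-12) return(M)
  M - u %*% (crossprod(u, M) / ss)
}

# Unpenalized refit on the stable sets; weights embedded back into the full
# feature space with zeros outside the stable sets.
refit_stable <- function(X, Y, stable_x, stable_y, ridge_eps = 1e-6) {
  fit <- cca_unpenalized(X[, stable_x, drop = FALSE],
                         Y[, stable_y, drop = FALSE], ridge_eps = ridge_eps)
  wx <- setNames(numeric(ncol(X)), colnames(X))
  wy <- setNames(numeric(ncol(Y)), colnames(Y))
  wx[stable_x] <- fit$wx
  wy[stable_y] <- fit$wy
  list(fit = fit, wx = wx, wy = wy, r_train = fit$canonical_r)
}

#' Training-set permutation test with full re-selection
#'
#' For each permutation the symptom view's rows are shuffled and the complete
#' selection-plus-refit procedure (stability selection, then unpenalized CCA
#' on the stable sets) is re-run, building the null distribution of the
#' training canonical correlation.  Permutations in which stability selection
#' finds no stable features contribute `r_perm = 0` (conservative).
#'
#' @param X,Y training matrices.
#' @param config a [pipeline_config()].
#' @param r_obs observed training canonical correlation.
#' @param seed base seed; permutation `i` uses `seed + i`.
#' @return list: one-sided `p_perm = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`
#'   and the vector `r_perm`.
#' @export
permutation_test_train <- function(X, Y, config, r_obs, seed = config$seed) {
  X <- ft_values(X); Y <- ft_values(Y)
  n <- nrow(X)
  r_perm <- numeric(config$n_perm)
  for (i in seq_len(config$n_perm)) {
    set.seed(seed + i)
    Yp <- Y[sample.int(n), , drop = FALSE]
    ss <- stability_select(X, Yp, config, seed = seed + i)
    r_perm[i] <- if (ss$no_signal) 0 else {
      refit_stable(X, Yp, ss$stable_x, ss$stable_y, config$ridge_eps)$r_train
    }
  }
  list(p_perm = (1 + sum(r_perm >= r_obs)) / (1 + config$n_perm),
       r_perm = r_perm)
}

#' Out-of-sample evaluation under fixed weights
#'
#' Computes the test-set canonical correlation from the trained weights, then
#' permutes the rows of the symptom view only (weights are not re-estimated)
#' to obtain a one-sided permutation p value.
#'
#' @param weights list with full-space `wx`, `wy`.
#' @param X_test,Y_test held-out matrices.
#' @param n_perm number of permutations (0 = report `r_test` only, `p = NA`).
#' @param seed base seed.
#' @return list: `r_test`, `p_perm_test`, `r_perm`.
#' @export
evaluate_test <- function(weights, X_test, Y_test, n_perm = 1000L, seed = 1L) {
  X <- ft_values(X_test); Y <- ft_values(Y_test)
  if (!identical(names(weights$wx), colnames(X)) ||
      !identical(names(weights$wy), colnames(Y))) {
    stop("feature mismatch between trained weights and test columns")
  }
  r_test <- canonical_correlation(X, Y, weights$wx, weights$wy)
  if (n_perm < 1) {
    return(list(r_test = r_test, p_perm_test = NA_real_, r_perm = numeric(0)))
  }
  u <- as.numeric(X %*% weights$wx)
  v <- as.numeric(Y %*% weights$wy)
  r_perm <- numeric(n_perm)
  set.seed(seed)
  for (i in seq_len(n_perm)) r_perm[i] <- cor(u, v[sample.int(length(v))])
  list(r_test = r_test,
       p_perm_test = (1 + sum(r_perm >= r_test)) / (1 + n_perm),
       r_perm = r_perm)
}

#' Sequential multi-mode sparse CCA with stability selection and permutation
#' inference
#'
#' The full protocol: split participants into training and test sets;
#' stability-select sparse supports on the training set; refit an unpenalized
#' CCA on the stable sets; assess the training correlation by a permutation
#' test that re-runs selection and refit per permutation; evaluate the fixed
#' weights on the test set with a row-permutation test; if significant,
#' projection-deflate both views' training and test matrices with the refit
#' weights and search for the next mode; stop at non-significance, an empty
#' stable set, or `max_modes`.  BH-FDR is applied across the test p values of
#' all extracted modes.
#'
#' Views are standardized internally using training-set means and standard
#' deviations, so test-set variates are computed on the training scale.
#'
#' @param X environment-category matrix or [feature_table] (participants x
#'   categories).
#' @param Y symptom matrix or [feature_table].
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result`: per-mode records (stable sets
#'   and frequencies, embedded refit weights, `r_train`, `p_perm_train`,
#'   `r_test`, `p_perm_test`, `p_fdr`, training variates), `n_significant`,
#'   `train_ids`, `test_ids`, the config, and the termination reason.
#' @export
run_multi_mode <- function(X, Y, config = pipeline_config()) {
  Xv <- ft_values(X); Yv <- ft_values(Y)
  stopifnot(nrow(Xv) == nrow(Yv))
  ids <- rownames(Xv)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Xv)))
  sp <- split_train_test(ids, config$train_fraction, config$seed)
  tr <- match(sp$train_ids, ids); te <- match(sp$test_ids, ids)
  std <- function(M, rows) {
    mu <- colMeans(M[rows, , drop = FALSE])
    sdv <- apply(M[rows, , drop = FALSE], 2, sd)
    if (any(sdv == 0)) stop("zero-variance feature in training data")
    sweep(sweep(M, 2, mu), 2, sdv, "/")
  }
  Xs <- std(Xv, tr); Ys <- std(Yv, tr)
  Xtr <- Xs[tr, , drop = FALSE]; Xte <- Xs[te, , drop = FALSE]
  Ytr <- Ys[tr, , drop = FALSE]; Yte <- Ys[te, , drop = FALSE]

  modes <- list()
  reason <- "max_modes"
  for (k in seq_len(config$max_modes)) {
    seed_k <- config$seed + 1000L * k
    ss <- stability_select(Xtr, Ytr, config, seed = seed_k)
    if (ss$no_signal) { reason <- "no_stable_signal"; break }
    rf <- refit_stable(Xtr, Ytr, ss$stable_x, ss$stable_y, config$ridge_eps)
    pt <- permutation_test_train(Xtr, Ytr, config, rf$r_train,
                                 seed = seed_k + 1L)
    ev <- evaluate_test(list(wx = rf$wx, wy = rf$wy), Xte, Yte,
                        n_perm = config$n_perm, seed = seed_k + 2L)
    significant <- is.finite(ev$p_perm_test) && ev$p_perm_test < config$alpha_fdr
    modes[[k]] <- list(
      mode_index = k,
      stable_x = ss$stable_x, stable_y = ss$stable_y,
      freq_x = ss$freq_x, freq_y = ss$freq_y,
      wx = rf$wx, wy = rf$wy,
      r_train = rf$r_train, p_perm_train = pt$p_perm,
      r_test = ev$r_test, p_perm_test = ev$p_perm_test,
      variate_x_train = as.numeric(Xtr %*% rf$wx),
      variate_y_train = as.numeric(Ytr %*% rf$wy),
      significant_unadjusted = significant)
    if (!significant) { reason <- "non_significant"; break }
    ## orthogonalized projection deflation: remove the weight direction from
    ## the columns AND residualize rows on the extracted variate, so the next
    ## mode's variates are exactly uncorrelated with this one's
    Xtr <- projection_deflate(resid_on_variate(Xtr, Xtr %*% rf$wx), rf$wx)
    Xte <- projection_deflate(resid_on_variate(Xte, Xte %*% rf$wx), rf$wx)
    Ytr <- projection_deflate(resid_on_variate(Ytr, Ytr %*% rf$wy), rf$wy)
    Yte <- projection_deflate(resid_on_variate(Yte, Yte %*% rf$wy), rf$wy)
  }
  p_test <- vapply(modes, `[[`, numeric(1), "p_perm_test")
  p_fdr <- p.adjust(p_test, method = "BH")
  for (k in seq_along(modes)) modes[[k]]$p_fdr <- p_fdr[k]
  n_sig <- sum(vapply(modes, function(m)
    m$significant_unadjusted && m$p_fdr < config$alpha_fdr, logical(1)))
  structure(list(modes = modes, n_significant = n_sig,
                 train_ids = sp$train_ids, test_ids = sp$test_ids,
                 config = config, termination = reason,
                 X_train_std = Xs[tr, , drop = FALSE],
                 Y_train_std = Ys[tr, , drop = FALSE]),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d mode(s) extracted, %d significant (FDR < %.2f); stopped: %s\n",
              length(x$modes), x$n_significant, x$config$alpha_fdr, x$termination))
  for (m in x$modes) {
    cat(sprintf("  mode %d: |X| = %d, |Y| = %d, r_train = %.3f (p = %.4g), r_test = %.3f (p = %.4g, FDR %.4g)\n",
                m$mode_index, length(m$stable_x), length(m$stable_y),
                m$r_train, m$p_perm_train, m$r_test, m$p_perm_test, m$p_fdr))
  }
  invisible(x)
}

#' Cross-loading explained-variance decomposition across modes
#'
#' The cross-loading of category `j` on symptom variate `k` is their Pearson
#' correlation `rho_jk`; its squared value (x100) is the explained variance
#' (EV).  The fraction of explained variance (FEV) of symptom group `k`
#' attributed to profile `m` is
#' `100 * sum_{j in stable set m} rho_jk^2 / sum_{m'} sum_{j in stable set m'}
#' rho_jk^2`, so FEV sums to 100 per symptom group.
#'
#' @param X_categories matrix of environmental categories on the common
#'   participant set.
#' @param symptom_variates matrix (participants x modes) of symptom variates.
#' @param mode_feature_sets list (one per mode) of stable category names.
#' @return list: `crossloadings` (categories x modes), `ev` (percent),
#'   `fev` (modes x modes; rows = environmental profiles, columns = symptom
#'   groups, percent).
#' @export
crossloadings_ev_fev <- function(X_categories, symptom_variates,
                                 mode_feature_sets) {
  X <- ft_values(X_categories)
  V <- as.matrix(symptom_variates)
  K <- ncol(V)
  stopifnot(length(mode_feature_sets) == K, nrow(X) == nrow(V))
  rho <- cor(X, V)
  ev <- 100 * rho^2
  fev <- matrix(NA_real_, K, K,
                dimnames = list(paste0("profile", seq_len(K)),
                                paste0("symptom_group", seq_len(K))))
  for (k in seq_len(K)) {
    mass <- vapply(mode_feature_sets, function(s) sum(rho[s, k]^2), numeric(1))
    if (sum(mass) <= 0) stop("no crossloading mass for symptom group ", k)
    fev[, k] <- 100 * mass / sum(mass)
  }
  list(crossloadings = rho, ev = ev, fev = fev)
}

#' Robustness checks for a fitted sparse CCA pipeline
#'
#' Three re-invocations of the fitted model with altered sampling and no new
#' mathematics: (1) a subsample-size sweep refitting the first mode's stable
#' sets on bootstrap samples of 10-150% of the training set; (2) a
#' resample-with-replacement distribution of refit-loading correlations with
#' the original weights; (3) sex-stratified refits with cross-sex application
#' of the weights.
#'
#' @param X,Y the views passed to [run_multi_mode()].
#' @param config the [pipeline_config()] used.
#' @param result the fitted `pipeline_result` (mode 1 must exist).
#' @param sex optional 0/1 vector aligned with rows of `X` for the stratified
#'   check.
#' @param fractions subsample fractions (default `seq(0.1, 1.5, 0.1)`).
#' @param n_rep replicates per fraction and for the bootstrap check.
#' @param seed integer seed.
#' @return list of sub-reports: `subsample_sweep` (fraction, mean and sd of
#'   r, n used, skipped flag), `bootstrap_loadings` (correlations with the
#'   original weights), `sex_split` (per-stratum and cross-stratum r) or
#'   `NULL` when `sex` is absent.
#' @export
reliability_suite <- function(X, Y, config, result, sex = NULL,
                              fractions = seq(0.1, 1.5, 0.1), n_rep = 20L,
                              seed = 1L) {
  stopifnot(inherits(result, "pipeline_result"), length(result$modes) >= 1)
  m1 <- result$modes[[1]]
  Xtr <- result$X_train_std
  Ytr <- result$Y_train_std
  n_tr <- nrow(Xtr)
  min_n <- max(length(m1$stable_x), length(m1$stable_y)) + 2L
  set.seed(seed)
  sweep_rows <- lapply(fractions, function(f) {
    size <- round(f * n_tr)
    if (size < min_n) {
      return(data.frame(fraction = f, n = size, r_mean = NA, r_sd = NA,
                        skipped = TRUE))
    }
    rs <- replicate(n_rep, {
      idx <- sample.int(n_tr, size, replace = TRUE)
      refit_stable(Xtr[idx, , drop = FALSE], Ytr[idx, , drop = FALSE],
                   m1$stable_x, m1$stable_y, config$ridge_eps)$r_train
    })
    data.frame(fraction = f, n = size, r_mean = mean(rs), r_sd = sd(rs),
               skipped = FALSE)
  })
  subsample_sweep <- do.call(rbind, sweep_rows)

  boot_cor <- replicate(n_rep, {
    idx <- sample.int(n_tr, n_tr, replace = TRUE)
    rf <- refit_stable(Xtr[idx, , drop = FALSE], Ytr[idx, , drop = FALSE],
                       m1$stable_x, m1$stable_y, config$ridge_eps)
    wx <- rf$wx * sign(sum(rf$wx * m1$wx))
    cor(wx, m1$wx) # full embedded weight vectors
  })

  sex_split <- NULL
  if (!is.null(sex)) {
    ids <- rownames(ft_values(X))
    if (is.null(ids)) ids <- as.character(seq_len(nrow(ft_values(X))))
    sex_tr <- sex[match(result$train_ids, ids)]
    rs <- lapply(c(0, 1), function(s) {
      rows <- which(sex_tr == s)
      rf <- refit_stable(Xtr[rows, , drop = FALSE], Ytr[rows, , drop = FALSE],
                         m1$stable_x, m1$stable_y, config$ridge_eps)
      list(rows = rows, rf = rf)
    })
    cross <- vapply(1:2, function(i) {
      other <- rs[[3 - i]]
      canonical_correlation(Xtr[other$rows, , drop = FALSE],
                            Ytr[other$rows, , drop = FALSE],
                            rs[[i]]$rf$wx, rs[[i]]$rf$wy)
    }, numeric(1))
    sex_split <- list(r_by_sex = c(male = rs[[1]]$rf$r_train,
                                   female = rs[[2]]$rf$r_train),
                      r_cross = c(male_weights_on_female = cross[1],
                                  female_weights_on_male = cross[2]))
  }
  list(subsample_sweep = subsample_sweep, bootstrap_loadings = boot_cor,
       sex_split = sex_split)
}
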