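#' Rank-one multi-block sparse CCA (SGCCA-style)
#'
#' Maximizes `sum_{j<k} design[j,k] * cov(X_j w_j, X_k w_k)` by cyclic block
#' updates `w_j <- l1_unit(sum_k design[j,k] X_j' X_k w_k / (n-1))` with
#' per-block L1 bounds `s_j * sqrt(p_j)` and unit L2 norms (Horst scheme,
#' identity inner weighting).  The objective is monotone non-decreasing across
#' sweeps; initialization is deterministic (leading singular vector of the
#' concatenated cross-covariances per block).
#'
#' @param blocks list of column-standardized matrices with equal row counts.
#' @param sparsity scalar or per-block vector of sparsity parameters in
#'   `[1/sqrt(p_j), 1]`; `s = 1` removes the penalty.
#' @param design symmetric 0/1 connection matrix with zero diagonal; default
#'   fully connected.
#' @param tol convergence tolerance on the max weight change.
#' @param max_iter maximum sweeps.
#' @return list of class `mscca_weights`: `weights` (per-block named unit-L2
#'   vectors), `objective`, `objective_trace`, `iterations`, `converged`.
#' @export
sgcca_rank1 <- function(blocks, sparsity = 0.5, design = NULL, tol = 1e-6,
                        max_iter = 200L) {
  blocks <- lapply(blocks, ft_values)
  J <- length(blocks)
  stopifnot(J >= 2)
  n <- nrow(blocks[[1]])
  stopifnot(all(vapply(blocks, nrow, 0L) == n))
  if (is.null(design)) {
    design <- matrix(1, J, J) - diag(J)
  }
  stopifnot(isSymmetric(design), all(diag(design) == 0))
  ## connectivity check (graph must be connected)
  reach <- rep(FALSE, J); reach[1] <- TRUE
  for (i in seq_len(J)) reach <- reach | (design %*% reach > 0)
  if (!all(reach)) stop("disconnected block design")
  if (length(sparsity) == 1) sparsity <- rep(sparsity, J)
  p <- vapply(blocks, ncol, 0L)
  for (j in seq_len(J)) {
    if (sparsity[j] < 1 / sqrt(p[j]) - 1e-12 || sparsity[j] > 1) {
      stop("sparsity for block ", j, " must lie in [1/sqrt(p), 1]")
    }
  }
  C <- vector("list", J)
  for (j in seq_len(J)) {
    C[[j]] <- lapply(seq_len(J), function(k) {
      if (design[j, k] == 0) return(NULL)
      crossprod(blocks[[j]], blocks[[k]]) / (n - 1)
    })
  }
  w <- lapply(seq_len(J), function(j) {
    concat <- do.call(cbind, C[[j]][!vapply(C[[j]], is.null, TRUE)])
    u <- svd(concat, nu = 1, nv = 0)$u[, 1]
    u / sqrt(sum(u^2))
  })
  objective <- function(w) {
    s <- 0
    for (j in seq_len(J)) for (k in seq_len(J)) {
      if (k > j && design[j, k] != 0) {
        s <- s + design[j, k] * as.numeric(crossprod(w[[j]], C[[j]][[k]] %*% w[[k]]))
      }
    }
    s
  }
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    delta <- 0
    for (j in seq_len(J)) {
      a <- numeric(p[j])
      for (k in seq_len(J)) {
        if (design[j, k] != 0) a <- a + design[j, k] * (C[[j]][[k]] %*% w[[k]])
      }
      w_new <- l1_unit(as.numeric(a), sparsity[j] * sqrt(p[j]))
      delta <- max(delta, max(abs(w_new - w[[j]])))
      w[[j]] <- w_new
    }
    trace <- c(trace, objective(w))
    if (delta < tol) { converged <- TRUE; break }
  }
  for (j in seq_len(J)) names(w[[j]]) <- colnames(blocks[[j]])
  structure(list(weights = w, objective = objective(w),
                 objective_trace = trace, iterations = iters,
                 converged = converged, design = design, sparsity = sparsity),
            class = "mscca_weights")
}

# Multi-block stability selection: per-block non-zero frequencies over
# half-sample resamples of the rank-one SGCCA.
mscca_stability <- function(blocks, config, design, seed) {
  n <- nrow(blocks[[1]])
  m <- max(2L, floor(config$resample_fraction * n))
  set.seed(seed)
  freq <- lapply(blocks, function(b) setNames(numeric(ncol(b)), colnames(b)))
  for (r in seq_len(config$n_resamples)) {
    idx <- sample.int(n, m)
    sub <- lapply(blocks, function(b) b[idx, , drop = FALSE])
    ## looser inner tolerance: only the non-zero pattern matters here
    fit <- sgcca_rank1(sub, sparsity = config$sparsity, design = design,
                       tol = 1e-5, max_iter = 60L)
    for (j in seq_along(blocks)) {
      freq[[j]] <- freq[[j]] + (abs(fit$weights[[j]]) > 1e-8)
    }
  }
  freq <- lapply(freq, function(f) f / config$n_resamples)
  stable <- lapply(freq, function(f) names(f)[f >= config$stability_threshold])
  list(freq = freq, stable = stable,
       no_signal = any(lengths(stable) == 0))
}

# Refit without sparsity on the stable sets; weights embedded in full space.
mscca_refit <- function(blocks, stable, design) {
  sub <- lapply(seq_along(blocks), function(j) {
    blocks[[j]][, stable[[j]], drop = FALSE]
  })
  fit <- sgcca_rank1(sub, sparsity = 1, design = design)
  w_full <- lapply(seq_along(blocks), function(j) {
    w <- setNames(numeric(ncol(blocks[[j]])), colnames(blocks[[j]]))
    w[stable[[j]]] <- fit$weights[[j]]
    w
  })
  list(fit = fit, weights = w_full)
}

mscca_pairwise_r <- function(blocks, weights) {
  v <- lapply(seq_along(blocks), function(j) as.numeric(blocks[[j]] %*% weights[[j]]))
  J <- length(v)
  out <- matrix(NA_real_, J, J)
  for (j in seq_len(J)) for (k in seq_len(J)) {
    if (k > j) out[j, k] <- out[k, j] <- cor(v[[j]], v[[k]])
  }
  out
}

#' Three-block stability-selected sparse CCA pipeline
#'
#' Same orchestration as [run_multi_mode()] with three views (environmental
#' profiles, regional brain volumes, symptom groups): per-block stability
#' selection at an 85% threshold by default, unpenalized multi-block refit on
#' the stable sets, permutation of the symptom block (full re-selection and
#' refit per permutation, gate statistic = design-weighted sum of pairwise
#' variate correlations), projection deflation of every block, and BH-FDR
#' across modes.  All three pairwise correlations are reported per mode in
#' training and test data, with per-pair permutation p values.
#'
#' @param env,brain,symptoms matrices or [feature_table]s on a common
#'   participant set; the brain view should be residualized including total
#'   intracranial volume beforehand.
#' @param config a [pipeline_config()]; `stability_threshold` defaults to
#'   0.85 here if the config still carries the two-block default of 0.90 and
#'   `relax_threshold` is `TRUE`.
#' @param design optional connection matrix (default fully connected).
#' @param relax_threshold replace a 0.90 threshold by the three-block default
#'   0.85 (set `FALSE` to keep the configured value).
#' @return object of class `mscca_result` with per-mode records: stable sets,
#'   weights, pairwise train/test correlation matrices (blocks ordered env,
#'   brain, symptoms), objective, permutation and FDR p values.
#' @export
run_mscca_pipeline <- function(env, brain, symptoms, config = pipeline_config(),
                               design = NULL, relax_threshold = TRUE) {
  blocks0 <- list(env = ft_values(env), brain = ft_values(brain),
                  symptoms = ft_values(symptoms))
  if (relax_threshold && config$stability_threshold == 0.9) {
    config$stability_threshold <- 0.85
  }
  J <- length(blocks0)
  if (is.null(design)) design <- matrix(1, J, J) - diag(J)
  n <- nrow(blocks0[[1]])
  ids <- rownames(blocks0[[1]])
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sp <- split_train_test(ids, config$train_fraction, config$seed)
  tr <- match(sp$train_ids, ids); te <- match(sp$test_ids, ids)
  std <- function(M) {
    mu <- colMeans(M[tr, , drop = FALSE])
    sdv <- apply(M[tr, , drop = FALSE], 2, sd)
    sweep(sweep(M, 2, mu), 2, sdv, "/")
  }
  Bstd <- lapply(blocks0, std)
  Btr <- lapply(Bstd, function(M) M[tr, , drop = FALSE])
  Bte <- lapply(Bstd, function(M) M[te, , drop = FALSE])

  sym_idx <- J  # permuted block
  gate_stat <- function(blocks, weights) {
    R <- mscca_pairwise_r(blocks, weights)
    sum(design[upper.tri(design)] * R[upper.tri(R)])
  }
  modes <- list()
  reason <- "max_modes"
  for (k in seq_len(config$max_modes)) {
    seed_k <- config$seed + 1000L * k
    ss <- mscca_stability(Btr, config, design, seed = seed_k)
    if (ss$no_signal) { reason <- "no_stable_signal"; break }
    rf <- mscca_refit(Btr, ss$stable, design)
    R_train <- mscca_pairwise_r(Btr, rf$weights)
    obs <- gate_stat(Btr, rf$weights)
    ## training permutation: shuffle symptom rows, redo selection + refit
    stat_perm <- numeric(config$n_perm)
    pair_perm <- matrix(0, config$n_perm, 3)
    for (i in seq_len(config$n_perm)) {
      set.seed(seed_k + i)
      Bp <- Btr
      Bp[[sym_idx]] <- Bp[[sym_idx]][sample.int(nrow(Bp[[sym_idx]])), , drop = FALSE]
      ssp <- mscca_stability(Bp, config, design, seed = seed_k + i)
      if (ssp$no_signal) { stat_perm[i] <- 0; next }
      rfp <- mscca_refit(Bp, ssp$stable, design)
      stat_perm[i] <- gate_stat(Bp, rfp$weights)
      Rp <- mscca_pairwise_r(Bp, rfp$weights)
      pair_perm[i, ] <- abs(Rp[upper.tri(Rp)])
    }
    p_train <- (1 + sum(stat_perm >= obs)) / (1 + config$n_perm)
    obs_pairs <- abs(R_train[upper.tri(R_train)])
    p_pairs_train <- vapply(1:3, function(j)
      (1 + sum(pair_perm[, j] >= obs_pairs[j])) / (1 + config$n_perm), numeric(1))
    ## test evaluation under fixed weights, permuting the symptom block rows
    R_test <- mscca_pairwise_r(Bte, rf$weights)
    obs_test <- gate_stat(Bte, rf$weights)
    stat_perm_te <- numeric(config$n_perm)
    set.seed(seed_k + 500000L)
    for (i in seq_len(config$n_perm)) {
      Bp <- Bte
      Bp[[sym_idx]] <- Bp[[sym_idx]][sample.int(nrow(Bp[[sym_idx]])), , drop = FALSE]
      stat_perm_te[i] <- gate_stat(Bp, rf$weights)
    }
    p_test <- (1 + sum(stat_perm_te >= obs_test)) / (1 + config$n_perm)
    significant <- p_test < config$alpha_fdr
    pair_names <- c("env_brain", "env_symptoms", "brain_symptoms")
    modes[[k]] <- list(
      mode_index = k,
      stable = ss$stable, freq = ss$freq, weights = rf$weights,
      objective = rf$fit$objective,
      r_train = setNames(R_train[upper.tri(R_train)], pair_names),
      r_test = setNames(R_test[upper.tri(R_test)], pair_names),
      p_perm_train = p_train,
      p_pairs_train = setNames(p_pairs_train, pair_names),
      p_perm_test = p_test,
      significant_unadjusted = significant)
    if (!significant) { reason <- "non_significant"; break }
    ## orthogonalized projection deflation per block (as in run_multi_mode)
    for (j in seq_len(J)) {
      w_j <- rf$weights[[j]]
      Btr[[j]] <- projection_deflate(
        resid_on_variate(Btr[[j]], Btr[[j]] %*% w_j), w_j)
      Bte[[j]] <- projection_deflate(
        resid_on_variate(Bte[[j]], Bte[[j]] %*% w_j), w_j)
    }
  }
  p_test_all <- vapply(modes, `[[`, numeric(1), "p_perm_test")
  p_fdr <- p.adjust(p_test_all, "BH")
  for (k in seq_along(modes)) modes[[k]]$p_fdr <- p_fdr[k]
  n_sig <- sum(vapply(modes, function(m)
    m$significant_unadjusted && m$p_fdr < config$alpha_fdr, logical(1)))
  structure(list(modes = modes, n_significant = n_sig,
                 train_ids = sp$train_ids, test_ids = sp$test_ids,
                 config = config, termination = reason),
            class = "mscca_result")
}

#' @export
print.mscca_result <- function(x, ...) {
  cat(sprintf("mscca_result: %d mode(s), %d significant; stopped: %s\n",
              length(x$modes), x$n_significant, x$termination))
  for (m in x$modes) {
    cat(sprintf("  mode %d: r_train(env-brain) = %.3f, r_train(brain-sym) = %.3f, p_perm = %.4g\n",
                m$mode_index, m$r_train["env_brain"], m$r_train["brain_symptoms"],
                m$p_perm_train))
  }
  invisible(x)
}
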