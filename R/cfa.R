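#' One-factor confirmatory factor analysis by maximum likelihood
#'
#' Fits the measurement model `Sigma(theta) = lambda lambda' + diag(psi)` to
#' the complete-case sample covariance of the items, minimizing the normal-
#' theory discrepancy
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p`
#' over loadings and uniquenesses (factor variance fixed to 1 for
#' identification; all loadings free).  Optimization is L-BFGS-B over
#' `(lambda, log psi)` with an analytic gradient; uniquenesses are floored at
#' 1e-6 (Heywood cases flagged, not fatal).  Sign convention: the loading sum
#' is non-negative.
#'
#' @param items a [feature_table] or numeric matrix of indicator items
#'   (>= 3 columns, more rows than columns after complete-case restriction).
#' @param max_iter maximum optimizer iterations.
#' @return An object of class `cfa_model`: item names, `loadings`,
#'   `uniquenesses`, implied covariance `Sigma`, sample covariance `S`, item
#'   means, `n_fit`, `fml`, `chi2`, `df`, fit indices (`tli`, `cfi`, `rmsea`,
#'   `srmr`, baseline chi-squared), `converged`, `grad_norm`, `heywood`.
#' @export
fit_cfa_one_factor <- function(items, max_iter = 500L) {
  v <- ft_values(items)
  p <- ncol(v)
  if (p < 3) stop("one-factor CFA needs at least 3 items for positive df")
  keep <- complete.cases(v)
  v <- v[keep, , drop = FALSE]
  n <- nrow(v)
  if (n <= p) stop("need more observations than items (n = ", n, ", p = ", p, ")")
  S <- cov(v)
  fit <- cfa_fit_cov(S, n, max_iter = max_iter)
  fit$item_names <- colnames(v)
  fit$means <- colMeans(v)
  names(fit$loadings) <- colnames(v)
  names(fit$uniquenesses) <- colnames(v)
  fit
}

# Core ML fit on a covariance matrix.
cfa_fit_cov <- function(S, n, max_iter = 500L) {
  p <- ncol(S)
  ldS <- determinant(S, logarithm = TRUE)$modulus
  if (!is.finite(ldS)) stop("singular sample covariance")

  unpack <- function(par) list(lam = par[1:p], psi = exp(par[(p + 1):(2 * p)]))
  fml <- function(par) {
    th <- unpack(par)
    Sg <- tcrossprod(th$lam) + diag(th$psi, p)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    Si <- chol2inv(ch)
    as.numeric(ld + sum(Si * S) - ldS - p)
  }
  grad <- function(par) {
    th <- unpack(par)
    Sg <- tcrossprod(th$lam) + diag(th$psi, p)
    Si <- tryCatch(chol2inv(chol(Sg)), error = function(e) NULL)
    if (is.null(Si)) return(rep(0, 2 * p))
    G <- Si %*% (Sg - S) %*% Si            # dF/dSigma
    g_lam <- 2 * as.numeric(G %*% th$lam)
    g_psi <- diag(G) * th$psi              # chain rule through log psi
    c(g_lam, g_psi)
  }

  ev <- eigen(S, symmetric = TRUE)
  lam0 <- ev$vectors[, 1] * sqrt(max(ev$values[1] * 0.7, 0.05))
  psi0 <- pmax(diag(S) - lam0^2, 0.05 * diag(S), 1e-4)
  par0 <- c(lam0, log(psi0))
  lower <- c(rep(-Inf, p), rep(log(1e-6), p))
  opt <- optim(par0, fml, grad, method = "L-BFGS-B", lower = lower,
               control = list(maxit = max_iter, factr = 1e4))
  th <- unpack(opt$par)
  if (sum(th$lam) < 0) th$lam <- -th$lam
  heywood <- any(th$psi <= 1.5e-6)
  Sg <- tcrossprod(th$lam) + diag(th$psi, p)
  f <- opt$value
  df <- p * (p + 1) / 2 - 2 * p
  chi2 <- (n - 1) * f
  gn <- sqrt(sum(grad(opt$par)^2))
  model <- structure(list(
    loadings = th$lam, uniquenesses = th$psi, Sigma = Sg, S = S,
    n_fit = n, fml = f, chi2 = chi2, df = df,
    converged = opt$convergence == 0, grad_norm = gn, heywood = heywood),
    class = "cfa_model")
  model$fit <- if (df > 0) {
    cfa_fit_indices(model, S, n)
  } else {
    ## just-identified model (p = 3): incremental/absolute indices undefined
    list(chi2 = chi2, df = df, chi2_baseline = NA_real_,
         df_baseline = p * (p - 1) / 2, cfi = NA_real_, tli = NA_real_,
         rmsea = NA_real_, srmr = NA_real_)
  }
  model
}

#' @export
print.cfa_model <- function(x, ...) {
  cat(sprintf("one-factor CFA: %d items, n = %d, chi2(%d) = %.3f\n",
              length(x$loadings), x$n_fit, x$df, x$chi2))
  cat(sprintf("  CFI %.4f  TLI %.4f  RMSEA %.4f  SRMR %.4f%s\n",
              x$fit$cfi, x$fit$tli, x$fit$rmsea, x$fit$srmr,
              if (x$heywood) "  [Heywood]" else ""))
  invisible(x)
}

#' Incremental and absolute fit indices for a fitted one-factor model
#'
#' The baseline is the independence model `Sigma_b = diag(S)` with
#' `chi2_b = (n-1) * (-log|R|)` and `df_b = p(p-1)/2`.  Formulas:
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`,
#' `TLI = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`,
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`, and SRMR is the root
#' mean square of the standardized residuals `(s_ij - sigma_ij) /
#' sqrt(s_ii s_jj)` over the lower triangle including the diagonal.
#'
#' @param model a `cfa_model` (or list with `chi2`, `df`, `Sigma`).
#' @param S sample covariance the model was fitted to.
#' @param n sample size.
#' @param chi2_baseline,df_baseline baseline-model statistics; computed from
#'   `S` when `NULL` (the default).
#' @return list: chi2, df, chi2_baseline, df_baseline, cfi, tli, rmsea, srmr.
#' @export
cfa_fit_indices <- function(model, S, n, chi2_baseline = NULL,
                            df_baseline = NULL) {
  p <- ncol(S)
  df <- model$df
  if (df <= 0) stop("fit indices undefined at df = 0")
  chi2 <- model$chi2
  Dh <- 1 / sqrt(diag(S))
  if (is.null(chi2_baseline)) {
    R <- S * tcrossprod(Dh)
    chi2_baseline <- (n - 1) *
      -as.numeric(determinant(R, logarithm = TRUE)$modulus)
  }
  if (is.null(df_baseline)) df_baseline <- p * (p - 1) / 2
  chi2_b <- chi2_baseline
  df_b <- df_baseline
  num <- max(chi2 - df, 0)
  cfi <- 1 - num / max(chi2_b - df_b, chi2 - df, 0)
  tli <- ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  resid_std <- (S - model$Sigma) * tcrossprod(Dh)
  lower <- resid_std[lower.tri(resid_std, diag = TRUE)]
  srmr <- sqrt(mean(lower^2))
  list(chi2 = chi2, df = df, chi2_baseline = chi2_b, df_baseline = df_b,
       cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr)
}

#' Iteratively prune items until the one-factor model fits well
#'
#' Fits the one-factor model, checks the excellent-fit criteria
#' (TLI > 0.95, CFI > 0.95, RMSEA < 0.06, SRMR < 0.08 by default) and, when
#' unmet, removes the item with the smallest absolute loading and refits,
#' stopping at success or at `min_items`.
#'
#' @param items a [feature_table] or matrix of items.
#' @param criteria named list of thresholds `tli`, `cfi`, `rmsea`, `srmr`.
#' @param min_items smallest admissible item count (default 3).
#' @return the accepted `cfa_model` with attribute `trail` (data frame of the
#'   pruning history: items retained, dropped item, fit indices per step).
#'   If the criteria are never met, an error carrying the best model found.
#' @export
cfa_item_prune <- function(items,
                           criteria = list(tli = 0.95, cfi = 0.95,
                                           rmsea = 0.06, srmr = 0.08),
                           min_items = 3L) {
  v <- ft_values(items)
  if (ncol(v) < min_items) stop("fewer items than min_items")
  trail <- list()
  best <- NULL
  repeat {
    model <- fit_cfa_one_factor(v)
    ## undefined indices (df = 0) never satisfy the criteria
    ok <- isTRUE(model$fit$tli > criteria$tli && model$fit$cfi > criteria$cfi &&
                   model$fit$rmsea < criteria$rmsea &&
                   model$fit$srmr < criteria$srmr)
    trail[[length(trail) + 1]] <- data.frame(
      n_items = ncol(v), cfi = model$fit$cfi, tli = model$fit$tli,
      rmsea = model$fit$rmsea, srmr = model$fit$srmr, accepted = ok,
      dropped = NA_character_, stringsAsFactors = FALSE)
    if (is.null(best) ||
        isTRUE(model$fit$srmr < best$fit$srmr) ||
        is.na(best$fit$srmr)) best <- model
    if (ok) {
      attr(model, "trail") <- do.call(rbind, trail)
      return(model)
    }
    if (ncol(v) <= min_items) {
      trail_df <- do.call(rbind, trail)
      cond <- structure(class = c("stabcca_prune_error", "error", "condition"),
                        list(message = "fit criteria never met at min_items",
                             call = sys.call(-1), best_model = best,
                             trail = trail_df))
      stop(cond)
    }
    drop_item <- names(model$loadings)[which.min(abs(model$loadings))]
    trail[[length(trail)]]$dropped <- drop_item
    v <- v[, setdiff(colnames(v), drop_item), drop = FALSE]
  }
}

#' Regression-method factor scores from a fitted one-factor model
#'
#' `f = lambda' Sigma(theta)^-1 (x - mean_train)`; centering statistics come
#' from the fitting sample, so scoring is deterministic and valid out of fold.
#'
#' @param model a `cfa_model`.
#' @param new_items a [feature_table] or matrix whose columns match
#'   `model$item_names`.
#' @return numeric vector of latent scores, named by participant.
#' @export
cfa_scores <- function(model, new_items) {
  v <- ft_values(new_items)
  miss <- setdiff(model$item_names, colnames(v))
  if (length(miss) > 0) stop("new_items lack model items: ", paste(miss, collapse = ", "))
  v <- v[, model$item_names, drop = FALSE]
  Si <- solve(model$Sigma)
  w <- as.numeric(crossprod(model$loadings, Si))
  centered <- sweep(v, 2, model$means)
  as.numeric(centered %*% w)
}

#' Collapse raw items into latent environmental categories out of fold
#'
#' Single-item categories are copied through unchanged.  For each multi-item
#' category the participants are split into `n_folds` folds; for every fold
#' the pruning loop ([cfa_item_prune()]) is fitted on the other folds and the
#' held-out participants are scored with the resulting model, so every latent
#' value is produced exactly once and never uses its own participant in
#' estimation.
#'
#' @param raw_env a [feature_table] of raw environment items.
#' @param specs list of category specs: each a list with `category_name` and
#'   `member_item_names` (single name = copy-through).  Specs must partition
#'   the raw items.
#' @param n_folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param criteria,min_items passed to [cfa_item_prune()].
#' @return a [feature_table] of category scores, columns ordered as `specs`,
#'   with attribute `models` (per-category, per-fold pruning summaries).
#' @export
build_categories <- function(raw_env, specs, n_folds = 10L, seed = 1L,
                             criteria = list(tli = 0.95, cfi = 0.95,
                                             rmsea = 0.06, srmr = 0.08),
                             min_items = 3L) {
  v <- ft_values(raw_env)
  all_items <- unlist(lapply(specs, `[[`, "member_item_names"))
  if (anyDuplicated(all_items) || !setequal(all_items, colnames(v))) {
    stop("category specs must partition the raw item list")
  }
  n <- nrow(v)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  out <- matrix(NA_real_, n, length(specs),
                dimnames = list(rownames(v),
                                vapply(specs, `[[`, "", "category_name")))
  models <- vector("list", length(specs))
  names(models) <- colnames(out)
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    items <- sp$member_item_names
    if (length(items) == 1) {
      out[, ci] <- v[, items]
      next
    }
    fold_models <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      train <- fold != f
      model <- tryCatch(
        cfa_item_prune(v[train, items, drop = FALSE],
                       criteria = criteria, min_items = min_items),
        stabcca_prune_error = function(e) {
          stop("category '", sp$category_name, "', fold ", f, ": ",
               conditionMessage(e))
        })
      stopifnot(model$n_fit <= sum(train)) # fold hygiene: no held-out rows in fit
      out[!train, ci] <- cfa_scores(model, v[!train, items, drop = FALSE])
      fold_models[[f]] <- list(items = model$item_names, fit = model$fit)
    }
    models[[ci]] <- fold_models
  }
  res <- feature_table(out, view_label = "environment_categories")
  attr(res, "models") <- models
  res
}
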