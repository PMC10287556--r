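#' Specification of a moderated-mediation analysis
#'
#' The moderator acts on the a-path (exposure to mediator), the b-path
#' (mediator to outcome) and the direct path — the "Model 59" configuration:
#' \deqn{M = a_0 + a_1 X + a_2 W + a_3 XW + \gamma'C + e_M}
#' \deqn{Y = b_0 + c' X + c_2 W + c_3 XW + b_1 M + b_2 MW + \delta'C + e_Y}
#'
#' @param x,m,y,w column names of exposure, mediator, outcome, moderator.
#' @param covariates further covariate column names.
#' @param percentiles moderator percentiles for conditional effects
#'   (default 16/50/84).
#' @param B bootstrap replicates (default 5,000).
#' @param ci_level confidence level (default 0.95).
#' @param center mean-center X, W and M before forming products (default
#'   `TRUE`).
#' @param seed integer seed for the bootstrap.
#' @return list of class `model59_spec`.
#' @export
model59_spec <- function(x, m, y, w, covariates = character(0),
                         percentiles = c(16, 50, 84), B = 5000L,
                         ci_level = 0.95, center = TRUE, seed = 1L) {
  cols <- c(x, m, y, w, covariates)
  if (anyDuplicated(cols)) stop("model columns must be distinct")
  stopifnot(B >= 1, ci_level > 0, ci_level < 1)
  structure(as.list(environment()), class = "model59_spec")
}

# Complete-case, optionally centered analysis frame with product terms.
model59_frame <- function(data, spec) {
  data <- as.data.frame(data)
  cols <- c(spec$x, spec$m, spec$y, spec$w, spec$covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) stop("columns absent from data: ", paste(miss, collapse = ", "))
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  X <- d[[spec$x]]; M <- d[[spec$m]]; Y <- d[[spec$y]]; W <- d[[spec$w]]
  if (isTRUE(spec$center)) {
    X <- X - mean(X); W <- W - mean(W); M <- M - mean(M)
  }
  C <- if (length(spec$covariates) > 0) {
    as.matrix(d[spec$covariates])
  } else NULL
  list(X = X, M = M, Y = Y, W = W, C = C, n = length(X))
}

# Both structural OLS fits on index rows (bootstrap-ready).  A constant
# moderator degenerates to simple mediation: the W terms are dropped and
# their coefficients fixed at zero.
model59_solve <- function(fr, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(fr$n)
  X <- fr$X[rows]; M <- fr$M[rows]; Y <- fr$Y[rows]; W <- fr$W[rows]
  C <- if (is.null(fr$C)) NULL else fr$C[rows, , drop = FALSE]
  if (sd(W) == 0) {
    ZM <- cbind(1, X, C)
    ZY <- cbind(1, X, M, C)
    fm <- .lm.fit(ZM, M)
    fy <- .lm.fit(ZY, Y)
    if (fm$rank < ncol(ZM) || fy$rank < ncol(ZY)) stop("singular design")
    cm <- fm$coefficients; cy <- fy$coefficients
    ncov <- if (is.null(C)) 0 else ncol(C)
    return(list(a = c(a0 = cm[1], a1 = cm[2], a2 = 0, a3 = 0),
                b = c(b0 = cy[1], cp = cy[2], c2 = 0, c3 = 0,
                      b1 = cy[3], b2 = 0),
                cov_m = if (ncov) setNames(cm[2 + seq_len(ncov)], colnames(fr$C)),
                cov_y = if (ncov) setNames(cy[3 + seq_len(ncov)], colnames(fr$C)),
                sigma2_m = sum(fm$residuals^2) / (length(rows) - ncol(ZM)),
                sigma2_y = sum(fy$residuals^2) / (length(rows) - ncol(ZY))))
  }
  ZM <- cbind(1, X, W, X * W, C)
  ZY <- cbind(1, X, W, X * W, M, M * W, C)
  fm <- .lm.fit(ZM, M)
  fy <- .lm.fit(ZY, Y)
  if (fm$rank < ncol(ZM) || fy$rank < ncol(ZY)) stop("singular design")
  cm <- fm$coefficients
  cy <- fy$coefficients
  ncov <- if (is.null(C)) 0 else ncol(C)
  list(a = c(a0 = cm[1], a1 = cm[2], a2 = cm[3], a3 = cm[4]),
       b = c(b0 = cy[1], cp = cy[2], c2 = cy[3], c3 = cy[4],
             b1 = cy[5], b2 = cy[6]),
       cov_m = if (ncov) setNames(cm[4 + seq_len(ncov)], colnames(fr$C)),
       cov_y = if (ncov) setNames(cy[6 + seq_len(ncov)], colnames(fr$C)),
       sigma2_m = sum(fm$residuals^2) / (length(rows) - ncol(ZM)),
       sigma2_y = sum(fy$residuals^2) / (length(rows) - ncol(ZY)))
}

#' Fit the moderated-mediation regressions
#'
#' Two ordinary least-squares fits on the identical complete-case set:
#' mediator on exposure, moderator, their product and covariates; outcome on
#' exposure, moderator, exposure-moderator product, mediator,
#' mediator-moderator product and covariates.  Exposure, moderator and
#' mediator are mean-centered before products when `spec$center` is `TRUE`.
#'
#' @param data data frame holding the spec's columns.
#' @param spec a [model59_spec()].
#' @return object of class `model59_fit`: coefficient vectors `a`
#'   (mediator equation) and `b` (outcome equation), covariate coefficients,
#'   residual variances, `n`, and the moderator values at the spec's
#'   percentiles (computed on the analysis sample).
#' @export
fit_model59 <- function(data, spec) {
  fr <- model59_frame(data, spec)
  n_par <- 6 + length(spec$covariates)
  if (fr$n <= n_par) stop("n below parameter count")
  fit <- model59_solve(fr)
  fit$n <- fr$n
  fit$w_percentiles <- quantile(fr$W, spec$percentiles / 100, names = FALSE)
  names(fit$w_percentiles) <- paste0("p", spec$percentiles)
  fit$spec <- spec
  class(fit) <- "model59_fit"
  fit
}

#' @export
print.model59_fit <- function(x, ...) {
  cat(sprintf("model59_fit (n = %d)\n  a-path: a1 = %.4f, a3 = %.4f\n  b-path: b1 = %.4f, b2 = %.4f\n  direct: c' = %.4f, c3 = %.4f\n",
              x$n, x$a["a1"], x$a["a3"], x$b["b1"], x$b["b2"],
              x$b["cp"], x$b["c3"]))
  invisible(x)
}

#' Conditional indirect and direct effects at moderator values
#'
#' `indirect(w) = (a1 + a3 w)(b1 + b2 w)`; `direct(w) = c' + c3 w`.
#'
#' @param fit a `model59_fit`.
#' @param w_values moderator values; default: the fit's stored percentiles.
#' @return data frame: w, indirect, direct, total.
#' @export
conditional_effects <- function(fit, w_values = NULL) {
  if (is.null(w_values)) w_values <- fit$w_percentiles
  ind <- (fit$a[["a1"]] + fit$a[["a3"]] * w_values) *
    (fit$b[["b1"]] + fit$b[["b2"]] * w_values)
  dir <- fit$b[["cp"]] + fit$b[["c3"]] * w_values
  data.frame(w = as.numeric(w_values), indirect = as.numeric(ind),
             direct = as.numeric(dir), total = as.numeric(ind + dir),
             row.names = names(w_values))
}

#' Bias-corrected bootstrap inference for conditional indirect effects
#'
#' Draws `B` participant resamples with replacement, refits both structural
#' equations and recomputes the conditional indirect (and direct) effects at
#' the moderator percentiles each time.  Intervals are bias-corrected (BC, no
#' acceleration): with `z0 = qnorm(#\{theta* < theta_hat\} / B)` the bounds
#' are the bootstrap percentiles at `pnorm(2 z0 +/- z_{alpha/2})`.  A
#' conditional effect is flagged significant when its interval excludes zero.
#' Resamples with singular designs are redrawn (counted, capped at 100).
#'
#' @param data data frame.
#' @param spec a [model59_spec()]; `spec$B` below 1,000 triggers a warning.
#' @return object of class `mediation_result`: the point `fit`, `effects`
#'   (per-percentile estimate, BC CI, significance for indirect and direct
#'   effects), `eme_percent` (explained mediation effect at the median
#'   moderator percentile), and bootstrap diagnostics.
#' @export
bootstrap_bca_ci <- function(data, spec) {
  if (spec$B < 1000) {
    warning("B = ", spec$B, " bootstrap replicates; intervals below B = 1000 are unstable")
  }
  fr <- model59_frame(data, spec)
  fit <- fit_model59(data, spec)
  wv <- fit$w_percentiles
  point <- conditional_effects(fit, wv)
  set.seed(spec$seed)
  B <- spec$B
  th_ind <- matrix(NA_real_, B, length(wv))
  th_dir <- matrix(NA_real_, B, length(wv))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    for (attempt in 1:100) {
      rows <- sample.int(fr$n, fr$n, replace = TRUE)
      sol <- tryCatch(model59_solve(fr, rows), error = function(e) NULL)
      if (!is.null(sol)) break
      n_redrawn <- n_redrawn + 1L
      if (attempt == 100) stop("bootstrap resampling kept producing singular designs")
    }
    th_ind[b, ] <- (sol$a[["a1"]] + sol$a[["a3"]] * wv) *
      (sol$b[["b1"]] + sol$b[["b2"]] * wv)
    th_dir[b, ] <- sol$b[["cp"]] + sol$b[["c3"]] * wv
  }
  alpha <- 1 - spec$ci_level
  zc <- qnorm(1 - alpha / 2)
  bc_ci <- function(theta_star, theta_hat) {
    prop <- mean(theta_star < theta_hat)
    prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
    z0 <- qnorm(prop)
    probs <- pnorm(c(2 * z0 - zc, 2 * z0 + zc))
    quantile(theta_star, probs, names = FALSE, type = 7)
  }
  mk <- function(th, est) {
    ci <- t(vapply(seq_along(wv), function(j) bc_ci(th[, j], est[j]),
                   numeric(2)))
    data.frame(w = as.numeric(wv), estimate = est,
               lower = ci[, 1], upper = ci[, 2],
               significant = ci[, 1] > 0 | ci[, 2] < 0,
               row.names = names(wv))
  }
  structure(list(
    fit = fit,
    indirect = mk(th_ind, point$indirect),
    direct = mk(th_dir, point$direct),
    eme_percent = explained_mediation_effect(fit, wv[["p50"]]),
    B = B, ci_level = spec$ci_level, n_redrawn = n_redrawn,
    boot_indirect = th_ind), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result (B = %d, %.0f%% BC CI)\n", x$B, 100 * x$ci_level))
  cat("conditional indirect effects:\n")
  print(x$indirect, digits = 4)
  cat(sprintf("explained mediation effect at median moderator: %.2f%%\n",
              x$eme_percent))
  invisible(x)
}

#' Explained mediation effect (proportion mediated)
#'
#' `EME = 100 * indirect(w) / (indirect(w) + direct(w))`, evaluated at the
#' median moderator percentile by default.  Undefined (NA with a warning)
#' when the total effect is within 1e-6 of zero.
#'
#' @param fit a `model59_fit`.
#' @param w_median moderator value (default: the fit's stored median
#'   percentile).
#' @return percentage (possibly `NA`).
#' @export
explained_mediation_effect <- function(fit, w_median = NULL) {
  if (is.null(w_median)) w_median <- fit$w_percentiles[["p50"]]
  eff <- conditional_effects(fit, w_median)
  if (abs(eff$total) < 1e-6) {
    warning("total effect within 1e-6 of zero; EME undefined")
    return(NA_real_)
  }
  100 * eff$indirect / eff$total
}
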