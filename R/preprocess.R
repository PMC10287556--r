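#' Mask extreme values by the median-absolute-deviation rule
#'
#' For each feature, values farther than `k` raw MADs from the feature median
#' are set to missing.  The MAD is the unscaled median absolute deviation
#' (no 1.4826 normal-consistency factor) unless `scaled = TRUE`; median and
#' MAD are computed on the non-missing values.  Features with MAD = 0 are left
#' untouched and flagged.  Single-pass semantics: statistics are not
#' recomputed after masking.
#'
#' @param table a [feature_table] or numeric matrix.
#' @param k threshold in MAD units (default 4).
#' @param scaled use the normal-consistent MAD (x1.4826)?
#' @return list with `table` (filtered copy) and `report` (data frame per
#'   feature: median, mad, n_masked, mad_zero flag) plus attribute
#'   `second_pass_would_mask` stating whether re-applying the rule would mask
#'   further values.
#' @export
mad_filter <- function(table, k = 4, scaled = FALSE) {
  stopifnot(k > 0)
  v <- ft_values(table)
  if (is.null(colnames(v))) colnames(v) <- paste0("V", seq_len(ncol(v)))
  med <- numeric(ncol(v))
  madv <- numeric(ncol(v))
  n_masked <- integer(ncol(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    ok <- !is.na(x)
    if (!any(ok)) stop("feature '", colnames(v)[j], "' is all-missing")
    if (sum(ok) < 3) stop("feature '", colnames(v)[j], "' has fewer than 3 observed values")
    med[j] <- median(x[ok])
    madv[j] <- median(abs(x[ok] - med[j]))
    if (scaled) madv[j] <- madv[j] * 1.4826
    if (madv[j] > 0 && is.finite(k)) {
      bad <- ok & abs(x - med[j]) > k * madv[j]
      n_masked[j] <- sum(bad)
      v[bad, j] <- NA
    }
  }
  ## would a second pass (with recomputed statistics) mask more?
  second <- FALSE
  for (j in seq_len(ncol(v))) {
    if (madv[j] == 0 || !is.finite(k)) next
    x <- v[, j][!is.na(v[, j])]
    m2 <- median(x)
    d2 <- median(abs(x - m2))
    if (scaled) d2 <- d2 * 1.4826
    if (d2 > 0 && any(abs(x - m2) > k * d2)) { second <- TRUE; break }
  }
  report <- data.frame(feature = colnames(v), median = med, mad = madv,
                       n_masked = n_masked, mad_zero = madv == 0,
                       stringsAsFactors = FALSE)
  attr(report, "second_pass_would_mask") <- second
  out <- if (inherits(table, "feature_table")) {
    feature_table(v, view_label = table$view_label)
  } else v
  list(table = out, report = report)
}

#' Flag near-zero-variance features
#'
#' A feature is flagged when the ratio of the most common value's frequency to
#' the second most common is at least `freq_cut` AND the percentage of
#' distinct values is at most `unique_cut_pct`.  Zero-variance features are
#' always flagged.  Defaults mirror the widely used caret convention
#' (95/5 = 19 and 10%).
#'
#' @param table a [feature_table] or matrix.
#' @param freq_cut frequency-ratio cutoff (default 19).
#' @param unique_cut_pct percent-unique cutoff (default 10).
#' @return data frame per feature: freq_ratio, pct_unique, zero_var, nzv flag.
#' @export
near_zero_variance <- function(table, freq_cut = 19, unique_cut_pct = 10) {
  v <- ft_values(table)
  if (ncol(v) == 0 || nrow(v) == 0) stop("empty table")
  res <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j][!is.na(v[, j])]
    tab <- sort(table(x), decreasing = TRUE)
    zero_var <- length(tab) <= 1
    fr <- if (zero_var) Inf else as.numeric(tab[1] / tab[2])
    pu <- 100 * length(tab) / length(x)
    data.frame(freq_ratio = fr, pct_unique = pu, zero_var = zero_var,
               nzv = zero_var || (fr >= freq_cut && pu <= unique_cut_pct))
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(feature = colnames(v), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Residualize features on a confound design
#'
#' Replaces each feature by its least-squares residual on the confounds (with
#' an implicit intercept), optionally standardizing the residuals to mean 0,
#' sd 1.  Participants with incomplete confounds are dropped first; features
#' with missing values are fitted on their observed rows (residuals stay `NA`
#' where the feature is missing).
#'
#' @param table a [feature_table] or matrix of features.
#' @param confounds a [feature_table] or matrix of confounds aligned on
#'   participant IDs (complete cases required).
#' @param zscore standardize residuals? default `TRUE`.
#' @return a [feature_table] (or matrix) of residuals over the complete-case
#'   participants, with attribute `dropped_ids`.
#' @export
residualize <- function(table, confounds, zscore = TRUE) {
  v <- ft_values(table)
  z <- ft_values(confounds)
  common <- intersect(rownames(v), rownames(z))
  if (length(common) == 0) stop("no shared participants between table and confounds")
  z <- z[common, , drop = FALSE]
  keep <- if (ncol(z) == 0) rep(TRUE, length(common)) else complete.cases(z)
  dropped <- common[!keep]
  common <- common[keep]
  v <- v[common, , drop = FALSE]
  z <- z[common, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient confound design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  out <- v
  full <- complete.cases(v)
  ## fast path for fully observed features, per-column fallback otherwise
  if (all(full)) {
    out[] <- qr.resid(qrX, v)
  } else {
    for (j in seq_len(ncol(v))) {
      ok <- !is.na(v[, j])
      fit <- lm.fit(X[ok, , drop = FALSE], v[ok, j])
      out[ok, j] <- fit$residuals
      out[!ok, j] <- NA
    }
  }
  if (zscore) {
    for (j in seq_len(ncol(out))) {
      s <- sd(out[, j], na.rm = TRUE)
      if (is.na(s) || s == 0) stop("zero-variance residual in feature '",
                                   colnames(out)[j], "'")
      out[, j] <- (out[, j] - mean(out[, j], na.rm = TRUE)) / s
    }
  }
  res <- if (inherits(table, "feature_table")) {
    feature_table(out, view_label = table$view_label)
  } else out
  attr(res, "dropped_ids") <- dropped
  res
}

#' De-duplicate participants sharing a household signature
#'
#' Participants are grouped by exact equality on all `match_fields`; from each
#' multi-member group one member is retained, chosen uniformly at random with
#' the given seed.  Participants with missing values in any match field are
#' treated as singletons (with a warning).
#'
#' @param records a [feature_table] or data frame of household indicator
#'   fields.
#' @param match_fields column names that define a household signature.
#' @param seed integer seed for the random within-group choice.
#' @return list: `kept_ids`, `excluded_ids`, `n_groups` (multi-member
#'   households), `n_excluded`.
#' @export
dedup_households <- function(records, match_fields, seed = 1L) {
  df <- if (inherits(records, "feature_table")) {
    as.data.frame(records$values)
  } else as.data.frame(records)
  missing_fields <- setdiff(match_fields, colnames(df))
  if (length(missing_fields) > 0) {
    stop("match fields absent from records: ", paste(missing_fields, collapse = ", "))
  }
  ids <- rownames(df)
  key_df <- df[match_fields]
  incomplete <- !complete.cases(key_df)
  if (any(incomplete)) {
    warning(sum(incomplete), " participant(s) with missing match fields treated as singletons")
  }
  key <- do.call(paste, c(key_df, sep = "\r"))
  key[incomplete] <- paste0("\rsingleton\r", seq_len(sum(incomplete)))
  set.seed(seed)
  groups <- split(ids, key)
  kept <- vapply(groups, function(g) {
    if (length(g) == 1) g else g[sample.int(length(g), 1)]
  }, character(1))
  kept <- ids[ids %in% kept]  # restore input order
  list(kept_ids = kept,
       excluded_ids = setdiff(ids, kept),
       n_groups = sum(lengths(groups) > 1),
       n_excluded = length(ids) - length(kept))
}
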