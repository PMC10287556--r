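#' Configuration for the synthetic multi-view generator
#'
#' Defines the study conditions under which synthetic participant-level data
#' are generated: correlated environmental categories with latent single-factor
#' raw-item structure, sparse planted canonical modes shared between the
#' environment and symptom views, brain regions that partially mediate the
#' first mode, biallelic dosages in LD blocks, a gene score that moderates the
#' mediation a-path, and linear confound effects on all views.
#'
#' Planted canonical strength is calibrated exactly: each mode `k` uses two
#' latents `u_k` (environment side) and `v_k` (symptom side) whose latent
#' correlation is inflated to `r_k / sqrt(rel_x * rel_y)`, where `rel` is the
#' closed-form reliability of the optimal equal-weight composite of the
#' mode's support items, so the population first canonical correlation between
#' the views equals `r_k`.
#'
#' @param n_participants number of participants.
#' @param n_env_raw number of raw environment items (default 128).
#' @param n_env_categories number of environmental categories (default 53); the
#'   first `n_latent_categories` are multi-item latent categories, the rest are
#'   single-item.
#' @param n_latent_categories number of multi-item categories (default 19).
#' @param n_symptoms number of symptom items (default 21).
#' @param n_brain number of regional brain volumes (default 139).
#' @param mode_strengths planted canonical correlations `r_k`, strictly
#'   decreasing, each in (0,1); may be empty for a global null.
#' @param support_sizes list with numeric vectors `env` and `symptoms`, one
#'   entry per mode: number of non-zero loadings per view.  Supports are
#'   disjoint across modes within a view by construction.  Symptom-side
#'   supports default to small clusters (5 and 4) so that a unit-norm support
#'   vector respects the protocol's L1 bound `0.5 sqrt(q)` and the planted
#'   structure is recoverable in principle.
#' @param env_item_share,symptom_item_share variance-share range (length-2, or
#'   a scalar for a constant) of a support item explained by its mode latent;
#'   shares are linearly spaced across each support so planted loadings are
#'   heterogeneous, as in real item sets (exact ties would make the
#'   L1-bounded support non-unique).
#' @param raw_item_loading loading of raw environment items on their category.
#' @param n_snps,maf_range,ld_block_size,ld_rho genotype parameters; see
#'   [simulate_genotypes()].
#' @param dosage_continuous if `TRUE`, jitter integer dosages into expected
#'   counts clipped to `[0, 2]` (imputed-dosage emulation).
#' @param mediation_coefs named vector `(a1, a3, b1, b2, cp, c3)` of the
#'   moderated-mediation generator.
#' @param n_brain_support number of brain regions loading on the mediator.
#' @param brain_item_share variance share of a mediating brain region explained
#'   by the mediator latent.
#' @param confound_effect_scale standard deviation of the linear confound
#'   coefficients added to every view (0 disables confounding).
#' @param seed integer seed; all outputs are reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_views()], [simulate_genotypes()]
#' @export
sim_config <- function(n_participants,
                       n_env_raw = 128L,
                       n_env_categories = 53L,
                       n_latent_categories = 19L,
                       n_symptoms = 21L,
                       n_brain = 139L,
                       mode_strengths = c(0.3, 0.15),
                       support_sizes = list(env = c(8L, 6L), symptoms = c(5L, 4L)),
                       env_item_share = c(0.45, 0.75),
                       symptom_item_share = c(0.45, 0.75),
                       raw_item_loading = 0.75,
                       n_snps = 60L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10L,
                       ld_rho = 0.8,
                       dosage_continuous = FALSE,
                       mediation_coefs = c(a1 = 0.5, a3 = 0.2, b1 = 0.4,
                                           b2 = 0.1, cp = 0.2, c3 = 0),
                       n_brain_support = 10L,
                       brain_item_share = 0.5,
                       confound_effect_scale = 0.2,
                       seed = 1L) {
  k <- length(mode_strengths)
  if (k > 0) {
    stopifnot(all(mode_strengths > 0), all(mode_strengths < 1))
    if (k > 1 && any(diff(mode_strengths) >= 0)) {
      stop("mode_strengths must be strictly decreasing")
    }
    stopifnot(length(support_sizes$env) == k,
              length(support_sizes$symptoms) == k,
              all(support_sizes$env >= 2), all(support_sizes$symptoms >= 2))
    if (sum(support_sizes$env) > n_env_categories) {
      stop("environment supports overlap: total support exceeds n_env_categories")
    }
    if (sum(support_sizes$symptoms) > n_symptoms) {
      stop("symptom supports overlap: total support exceeds n_symptoms")
    }
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  stopifnot(n_participants >= 10, n_latent_categories <= n_env_categories,
            n_env_raw >= n_env_categories, ld_rho >= 0, ld_rho < 1,
            confound_effect_scale >= 0)
  mediation_coefs <- mediation_coefs[c("a1", "a3", "b1", "b2", "cp", "c3")]
  if (anyNA(mediation_coefs)) stop("mediation_coefs must name a1, a3, b1, b2, cp, c3")
  structure(as.list(environment()), class = "sim_config")
}

# Variance shares for a support of size m: linearly spaced across the
# configured range (strongest item first).
support_shares <- function(m, share) {
  if (length(share) == 1) rep(share, m) else seq(max(share), min(share), length.out = m)
}

# Reliability (squared multiple correlation) of the optimal composite of items
# x_j = sqrt(a_j) u + sqrt(1 - a_j) e_j for a unit-variance latent u:
# R^2 = S / (1 + S) with signal-to-noise sum S = sum a_j / (1 - a_j).
composite_reliability <- function(shares) {
  s <- sum(shares / (1 - shares))
  s / (1 + s)
}

# Standardized confound design used for planted confound effects (age, sex,
# center dummies; ICV appended for the brain view).
confound_design <- function(cov_values, with_icv = FALSE) {
  cols <- c("age", "sex", "center2", "center3", if (with_icv) "icv")
  scale(cov_values[, cols, drop = FALSE])
}

#' Generate linked multi-view synthetic data with known planted structure
#'
#' Draws environment categories, raw environment items, symptoms, brain
#' volumes, genotypes and covariates for `config$n_participants` participants.
#' Canonical modes are planted on disjoint supports so that the population
#' first canonical correlation of mode `k` equals `mode_strengths[k]`; part of
#' the first mode's shared variance is routed through a brain mediator whose
#' a-path is moderated by a gene score, and linear confound effects (age, sex,
#' center; ICV for brain) are added to all views.
#'
#' @param config a [sim_config()].
#' @return A list with elements `data` (class `sim_dataset`: feature tables
#'   `env` (raw items), `env_categories` (true category scores), `symptoms`,
#'   `brain`, `covariates`, plus `genotypes`) and `truth` (class `sim_truth`:
#'   planted weights, supports, latent draws, calibrated latent correlations,
#'   mediation coefficients, moderator genes, category membership specs).
#' @export
simulate_views <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genotypes(config)
  set.seed(config$seed)
  n <- config$n_participants
  K <- length(config$mode_strengths)
  p <- config$n_env_categories
  q <- config$n_symptoms

  ids <- sprintf("P%06d", seq_len(n))

  ## covariates
  age <- rnorm(n, 55, 7.5)
  sex <- rbinom(n, 1, 0.5)
  center <- sample(1:3, n, replace = TRUE)
  batch <- rbinom(n, 1, 0.5)
  pcs <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("PC", 1:10)))
  icv <- rnorm(n, 1500, 110)
  covariates <- cbind(age = age, sex = sex,
                      center2 = as.numeric(center == 2),
                      center3 = as.numeric(center == 3),
                      batch = batch, pcs, icv = icv)
  rownames(covariates) <- ids

  ## gene score moderator: total effect-allele burden over the first gene block
  moderator_genes <- unique(g$info$gene)[1]
  mod_snps <- g$info$id[g$info$gene %in% moderator_genes]
  W <- rowSums(g$dosages[, mod_snps, drop = FALSE])
  W <- as.numeric(scale(W))

  ## mode latents with calibrated latent correlation
  env_supports <- list()
  sym_supports <- list()
  r_latent <- numeric(K)
  U <- matrix(0, n, max(K, 1))
  V <- matrix(0, n, max(K, 1))
  e_next <- 1L
  s_next <- 1L
  mc <- config$mediation_coefs
  M_lat <- NULL
  for (k in seq_len(K)) {
    me <- config$support_sizes$env[k]
    ms <- config$support_sizes$symptoms[k]
    env_supports[[k]] <- seq(e_next, length.out = me)
    sym_supports[[k]] <- seq(s_next, length.out = ms)
    e_next <- e_next + me
    s_next <- s_next + ms
    rel <- composite_reliability(support_shares(me, config$env_item_share)) *
      composite_reliability(support_shares(ms, config$symptom_item_share))
    r_star <- config$mode_strengths[k] / sqrt(rel)
    if (r_star >= 0.999) {
      stop(sprintf("mode %d: calibrated latent correlation %.3f infeasible; increase support or item share", k, r_star))
    }
    r_latent[k] <- r_star
    u <- rnorm(n)
    if (k == 1 && mc[["a1"]] != 0) {
      ## route part of mode 1's shared variance through a brain mediator whose
      ## a-path is moderated by the gene score W
      M <- mc[["a1"]] * u + mc[["a3"]] * u * W + rnorm(n)
      sd_M <- sqrt(mc[["a1"]]^2 + mc[["a3"]]^2 + 1)
      M_std <- M / sd_M
      rho_m <- mc[["a1"]] / sd_M
      gam <- 0.5 * r_star / rho_m
      del <- r_star - gam * rho_m
      tau2 <- 1 - gam^2 - del^2 - 2 * gam * del * rho_m
      if (tau2 <= 0) { # fall back to direct correlation if infeasible
        gam <- 0
        del <- r_star
        tau2 <- 1 - r_star^2
        M_std <- M / sd_M
      }
      v <- gam * M_std + del * u + sqrt(tau2) * rnorm(n)
      M_lat <- M_std
    } else {
      v <- r_star * u + sqrt(1 - r_star^2) * rnorm(n)
    }
    U[, k] <- u
    V[, k] <- v
  }
  if (is.null(M_lat)) M_lat <- rnorm(n)

  ## environment categories and symptoms
  env_cat <- matrix(rnorm(n * p), n, p,
                    dimnames = list(ids, sprintf("env_cat%02d", seq_len(p))))
  sym <- matrix(rnorm(n * q), n, q,
                dimnames = list(ids, sprintf("symptom%02d", seq_len(q))))
  for (k in seq_len(K)) {
    ae <- support_shares(length(env_supports[[k]]), config$env_item_share)
    as_ <- support_shares(length(sym_supports[[k]]), config$symptom_item_share)
    for (i in seq_along(env_supports[[k]])) {
      j <- env_supports[[k]][i]
      env_cat[, j] <- sqrt(ae[i]) * U[, k] + sqrt(1 - ae[i]) * rnorm(n)
    }
    for (i in seq_along(sym_supports[[k]])) {
      j <- sym_supports[[k]][i]
      sym[, j] <- sqrt(as_[i]) * V[, k] + sqrt(1 - as_[i]) * rnorm(n)
    }
  }

  ## brain volumes: noisy indicators of the mediator latent
  nb <- config$n_brain
  brain <- matrix(rnorm(n * nb), n, nb,
                  dimnames = list(ids, sprintf("roi%03d", seq_len(nb))))
  brain_support <- seq_len(min(config$n_brain_support, nb))
  ab <- config$brain_item_share
  for (j in brain_support) {
    brain[, j] <- sqrt(ab) * M_lat + sqrt(1 - ab) * rnorm(n)
  }

  ## confound effects (linear, so residualization removes them exactly)
  cs <- config$confound_effect_scale
  add_confounds <- function(mat, with_icv = FALSE) {
    if (cs == 0) return(mat)
    Z <- confound_design(covariates, with_icv)
    B <- matrix(rnorm(ncol(Z) * ncol(mat), sd = cs), ncol(Z))
    mat + Z %*% B
  }
  env_cat <- add_confounds(env_cat)
  sym <- add_confounds(sym)
  brain <- add_confounds(brain, with_icv = TRUE)

  ## raw environment items: first n_latent_categories categories are
  ## multi-item (single-factor indicators), the rest copy through
  nl <- config$n_latent_categories
  n_multi_items <- config$n_env_raw - (p - nl)
  sizes <- rep(n_multi_items %/% nl, nl)
  extra <- n_multi_items %% nl
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  if (any(sizes < 2)) stop("n_env_raw too small for multi-item categories")
  lam <- config$raw_item_loading
  raw_cols <- list()
  specs <- list()
  for (j in seq_len(p)) {
    cat_name <- colnames(env_cat)[j]
    if (j <= nl) {
      m <- sizes[j]
      items <- sprintf("%s_item%d", cat_name, seq_len(m))
      block <- sapply(seq_len(m), function(i) {
        lam * env_cat[, j] + sqrt(1 - lam^2) * rnorm(n)
      })
      colnames(block) <- items
      raw_cols[[j]] <- block
      specs[[j]] <- list(category_name = cat_name, member_item_names = items)
    } else {
      item <- sprintf("%s_item1", cat_name)
      raw_cols[[j]] <- matrix(env_cat[, j], n, 1, dimnames = list(ids, item))
      specs[[j]] <- list(category_name = cat_name, member_item_names = item)
    }
  }
  env_raw <- do.call(cbind, raw_cols)
  rownames(env_raw) <- ids

  ## population canonical weights: w_j proportional to sqrt(a_j) / (1 - a_j)
  planted_weights <- lapply(seq_len(K), function(k) {
    ae <- support_shares(length(env_supports[[k]]), config$env_item_share)
    as_ <- support_shares(length(sym_supports[[k]]), config$symptom_item_share)
    wx <- numeric(p); wx[env_supports[[k]]] <- sqrt(ae) / (1 - ae)
    wy <- numeric(q); wy[sym_supports[[k]]] <- sqrt(as_) / (1 - as_)
    wx <- wx / sqrt(sum(wx^2)); wy <- wy / sqrt(sum(wy^2))
    list(env = setNames(wx, colnames(env_cat)),
         symptoms = setNames(wy, colnames(sym)))
  })

  data <- structure(list(
    env = feature_table(env_raw, view_label = "environment_raw"),
    env_categories = feature_table(env_cat, view_label = "environment_categories"),
    symptoms = feature_table(sym, view_label = "symptoms"),
    brain = feature_table(brain, view_label = "brain"),
    covariates = feature_table(covariates, view_label = "covariates"),
    genotypes = g), class = "sim_dataset")
  truth <- structure(list(
    planted_weights = planted_weights,
    planted_r = config$mode_strengths,
    latent_r = r_latent,
    env_supports = env_supports,
    sym_supports = sym_supports,
    brain_support = brain_support,
    latents = list(u = U[, seq_len(K), drop = FALSE],
                   v = V[, seq_len(K), drop = FALSE],
                   mediator = M_lat, moderator = W),
    mediation_coefs = mc,
    moderator_gene_ids = moderator_genes,
    category_specs = specs), class = "sim_truth")
  list(data = data, truth = truth)
}

#' Simulate biallelic dosages in LD blocks
#'
#' Haplotypes are drawn from a latent Gaussian AR(1) process within each LD
#' block (autocorrelation `ld_rho`), thresholded at the block's allele
#' frequencies; the diploid dosage is the sum of two independent haplotypes.
#' Blocks are contiguous in position, each annotated to one gene.
#'
#' @param config a [sim_config()].
#' @return A `genotype_matrix`: list with `dosages` (participants x variants,
#'   values in `[0, 2]`) and `info` (data frame: id, chrom, pos, effect_allele,
#'   other_allele, gene, maf (realized), info).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_snps >= 1)
  set.seed(config$seed + 1L)
  n <- config$n_participants
  m <- config$n_snps
  bs <- config$ld_block_size
  rho <- config$ld_rho
  n_blocks <- ceiling(m / bs)
  block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(m)]

  haplo <- function() {
    H <- matrix(0L, n, m)
    for (b in seq_len(n_blocks)) {
      cols <- which(block_of == b)
      z <- matrix(rnorm(n * length(cols)), n)
      if (rho > 0 && length(cols) > 1) {
        for (j in 2:length(cols)) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
      }
      H[, cols] <- (z < rep(qnorm(mafs[cols]), each = n)) + 0L
    }
    H
  }
  mafs <- runif(m, config$maf_range[1], config$maf_range[2])
  dos <- haplo() + haplo()
  if (isTRUE(config$dosage_continuous)) {
    dos <- pmin(pmax(dos + rnorm(n * m, sd = 0.05), 0), 2)
  }
  ids <- sprintf("P%06d", seq_len(n))
  vid <- sprintf("rs%05d", seq_len(m))
  dimnames(dos) <- list(ids, vid)

  chrom <- ((block_of - 1L) %% 22L) + 1L
  pos <- integer(m)
  for (b in seq_len(n_blocks)) {
    cols <- which(block_of == b)
    round_on_chrom <- (b - 1L) %/% 22L
    pos[cols] <- 1e6L * round_on_chrom + 5000L * seq_along(cols) + 1L
  }
  info <- data.frame(
    id = vid, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    gene = sprintf("GENE%02d", block_of),
    maf = colMeans(dos) / 2, info = 1.0,
    stringsAsFactors = FALSE)
  ## realized frequency may exceed 0.5; report minor allele frequency
  info$maf <- pmin(info$maf, 1 - info$maf)
  structure(list(dosages = dos, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d participants x %d variants, %d gene blocks\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$info$gene))))
  invisible(x)
}

#' Generate outcomes from the moderated-mediation structural model
#'
#' Structural equations: `M = a1 X + a3 X W + e_M` and
#' `Y = cp X + c3 X W + b1 M + b2 M W + e_Y` with standard-normal errors, where
#' `W` is the standardized gene score over the configured moderator genes.
#'
#' @param config a [sim_config()] carrying `mediation_coefs`.
#' @param env_profile numeric exposure vector (one value per participant).
#' @param genotypes a `genotype_matrix`; the moderator score is the summed
#'   dosage over the first gene block, standardized.
#' @param moderator_genes gene labels used for the score (default: first gene).
#' @return list with `brain_component` (the mediator `M`), `symptom_group`
#'   (`Y`), `moderator` (`W`) and `brain` (a feature table of noisy ROI
#'   indicators of `M`).
#' @export
simulate_moderated_mediation <- function(config, env_profile, genotypes,
                                         moderator_genes = NULL) {
  stopifnot(inherits(config, "sim_config"),
            length(env_profile) == config$n_participants)
  set.seed(config$seed + 2L)
  if (is.null(moderator_genes)) moderator_genes <- unique(genotypes$info$gene)[1]
  snps <- genotypes$info$id[genotypes$info$gene %in% moderator_genes]
  if (length(snps) == 0) stop("no variants annotated to the moderator genes")
  W <- as.numeric(scale(rowSums(genotypes$dosages[, snps, drop = FALSE])))
  co <- config$mediation_coefs
  X <- env_profile
  n <- length(X)
  M <- co[["a1"]] * X + co[["a3"]] * X * W + rnorm(n)
  Y <- co[["cp"]] * X + co[["c3"]] * X * W + co[["b1"]] * M + co[["b2"]] * M * W +
    rnorm(n)
  ab <- config$brain_item_share
  nb <- config$n_brain
  Ms <- as.numeric(scale(M))
  brain <- matrix(rnorm(n * nb), n, nb,
                  dimnames = list(sprintf("P%06d", seq_len(n)),
                                  sprintf("roi%03d", seq_len(nb))))
  for (j in seq_len(min(config$n_brain_support, nb))) {
    brain[, j] <- sqrt(ab) * Ms + sqrt(1 - ab) * rnorm(n)
  }
  list(brain_component = M, symptom_group = Y, moderator = W,
       brain = feature_table(brain, view_label = "brain"))
}

#' Write a simulated dataset and its generating truth to plain-text files
#'
#' Writes `env.tsv`, `env_categories.tsv`, `symptoms.tsv`, `brain.tsv`,
#' `covariates.tsv`, `genotypes.tsv`, `variants.tsv` and `truth.json`.
#'
#' @param sim result of [simulate_views()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- sim$data
  write_feature_table(d$env, file.path(dir, "env.tsv"))
  write_feature_table(d$env_categories, file.path(dir, "env_categories.tsv"))
  write_feature_table(d$symptoms, file.path(dir, "symptoms.tsv"))
  write_feature_table(d$brain, file.path(dir, "brain.tsv"))
  write_feature_table(d$covariates, file.path(dir, "covariates.tsv"))
  write_feature_table(d$genotypes$dosages, file.path(dir, "genotypes.tsv"))
  write.table(d$genotypes$info, file.path(dir, "variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  tr_json <- list(
    planted_r = tr$planted_r, latent_r = tr$latent_r,
    env_supports = tr$env_supports, sym_supports = tr$sym_supports,
    brain_support = tr$brain_support,
    mediation_coefs = as.list(tr$mediation_coefs),
    moderator_gene_ids = tr$moderator_gene_ids,
    planted_weights = lapply(tr$planted_weights, function(w)
      list(env = as.list(w$env), symptoms = as.list(w$symptoms))))
  jsonlite::write_json(tr_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
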