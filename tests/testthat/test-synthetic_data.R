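test_that("identical configurations reproduce bit-identical datasets", {
  cfg <- sim_config(n_participants = 300, n_snps = 20, seed = 99)
  a <- simulate_views(cfg)
  b <- simulate_views(cfg)
  expect_identical(a$data$env$values, b$data$env$values)
  expect_identical(a$data$symptoms$values, b$data$symptoms$values)
  expect_identical(a$data$genotypes$dosages, b$data$genotypes$dosages)
  expect_identical(a$truth$latents$u, b$truth$latents$u)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(300, mode_strengths = c(0.1, 0.3)), "decreasing")
  expect_error(sim_config(300, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(300, mode_strengths = 0.3,
                          support_sizes = list(env = 60, symptoms = 5)),
               "overlap")
})

test_that("all views share the participant index and dosages stay in [0, 2]", {
  cfg <- sim_config(n_participants = 400, n_snps = 30, seed = 5)
  sim <- simulate_views(cfg)
  ids <- rownames(sim$data$env$values)
  for (v in c("env_categories", "symptoms", "brain", "covariates")) {
    expect_identical(rownames(sim$data[[v]]$values), ids)
  }
  expect_identical(rownames(sim$data$genotypes$dosages), ids)
  expect_true(all(sim$data$genotypes$dosages >= 0 &
                    sim$data$genotypes$dosages <= 2))
  expect_false(anyNA(sim$data$env$values))
})

test_that("a null configuration produces independent views", {
  cfg <- sim_config(n_participants = 10000, mode_strengths = numeric(0),
                    support_sizes = list(env = numeric(0), symptoms = numeric(0)),
                    n_env_categories = 5L, n_symptoms = 5L,
                    n_latent_categories = 2L, n_env_raw = 11L,
                    confound_effect_scale = 0, seed = 12)
  sim <- simulate_views(cfg)
  r1 <- cancor(sim$data$env_categories$values, sim$data$symptoms$values)$cor[1]
  # largest of 5x5 null canonical correlations at n = 10,000 is ~ O(sqrt(p/n))
  expect_lt(r1, 0.08)
})

test_that("the planted first canonical correlation matches its target", {
  cfg <- sim_config(n_participants = 20000, mode_strengths = 0.3,
                    support_sizes = list(env = 8, symptoms = 5), seed = 7)
  sim <- simulate_views(cfg)
  tr <- sim$truth
  conf <- sim$data$covariates$values[, c("age", "sex", "center2", "center3")]
  Xr <- as.matrix(residualize(
    sim$data$env_categories$values[, tr$env_supports[[1]]], conf))
  Yr <- as.matrix(residualize(
    sim$data$symptoms$values[, tr$sym_supports[[1]]], conf))
  r <- cancor(Xr, Yr)$cor[1]
  expect_gt(r, 0.28)
  expect_lt(r, 0.32)
})

test_that("estimated canonical r is monotone in the planted strength", {
  rs <- vapply(c(0.05, 0.15, 0.3), function(r1) {
    cfg <- sim_config(n_participants = 20000, mode_strengths = r1,
                      support_sizes = list(env = 8, symptoms = 5),
                      confound_effect_scale = 0, seed = 42)
    sim <- simulate_views(cfg)
    tr <- sim$truth
    cancor(sim$data$env_categories$values[, tr$env_supports[[1]]],
           sim$data$symptoms$values[, tr$sym_supports[[1]]])$cor[1]
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("genotype LD structure follows the block autocorrelation", {
  # independent variants: negligible dosage correlation
  cfg0 <- sim_config(n_participants = 5000, n_snps = 46, ld_rho = 0,
                     ld_block_size = 23L, seed = 3)
  g0 <- simulate_genotypes(cfg0)
  cors <- cor(g0$dosages)
  off <- cors[upper.tri(cors)]
  expect_lt(mean(off^2), 0.01)

  # tight LD: adjacent dosages strongly correlated
  cfg9 <- sim_config(n_participants = 100000, n_snps = 10, ld_rho = 0.9,
                     maf_range = c(0.3, 0.5), seed = 3)
  g9 <- simulate_genotypes(cfg9)
  r2_adj <- cor(g9$dosages[, 1], g9$dosages[, 2])^2
  expect_gt(r2_adj, 0.4)
})

test_that("realized allele frequency concentrates at the configured MAF", {
  cfg <- sim_config(n_participants = 100000, n_snps = 4,
                    maf_range = c(0.5, 0.5), ld_rho = 0, seed = 8)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$dosages) / 2
  expect_true(all(freq > 0.497 & freq < 0.503))
})

test_that("variant annotations are positionally coherent", {
  cfg <- sim_config(n_participants = 200, n_snps = 50, ld_block_size = 10L,
                    seed = 2)
  g <- simulate_genotypes(cfg)
  expect_equal(nrow(g$info), 50)
  expect_true(all(g$info$info == 1))
  by_chr <- split(g$info$pos, g$info$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
  expect_equal(length(unique(g$info$gene)), 5)
})

test_that("the moderated-mediation generator honours its structural equations", {
  n <- 20000
  # null a- and b-paths: indirect effect indistinguishable from zero
  cfg0 <- sim_config(n, n_snps = 20,
                     mediation_coefs = c(a1 = 0, a3 = 0, b1 = 0, b2 = 0,
                                         cp = 0.2, c3 = 0), seed = 31)
  g <- simulate_genotypes(cfg0)
  x <- rnorm(n)
  out0 <- simulate_moderated_mediation(cfg0, x, g)
  a1_hat <- coef(lm(out0$brain_component ~ x))[2]
  b1_hat <- coef(lm(out0$symptom_group ~ out0$brain_component + x))[2]
  expect_lt(abs(a1_hat * b1_hat), 0.01)

  # a1 = 0.5, b1 = 0.4: product-of-coefficients near 0.2
  cfg1 <- sim_config(n, n_snps = 20,
                     mediation_coefs = c(a1 = 0.5, a3 = 0, b1 = 0.4, b2 = 0,
                                         cp = 0.2, c3 = 0), seed = 32)
  out1 <- simulate_moderated_mediation(cfg1, x, g)
  a1_hat <- coef(lm(out1$brain_component ~ x))[2]
  b1_hat <- coef(lm(out1$symptom_group ~ out1$brain_component + x))[2]
  expect_gt(a1_hat * b1_hat, 0.17)
  expect_lt(a1_hat * b1_hat, 0.23)
})

test_that("a-path moderation shifts the indirect effect by 2 a3 b1 across w = -1, 1", {
  n <- 50000
  cfg <- sim_config(n, n_snps = 20,
                    mediation_coefs = c(a1 = 0.5, a3 = 0.2, b1 = 0.4, b2 = 0,
                                        cp = 0, c3 = 0), seed = 33)
  g <- simulate_genotypes(cfg)
  x <- rnorm(n)
  out <- simulate_moderated_mediation(cfg, x, g)
  d <- data.frame(x = x, m = out$brain_component, y = out$symptom_group,
                  w = out$moderator)
  fit <- fit_model59(d, model59_spec("x", "m", "y", "w", B = 1, center = FALSE))
  eff <- conditional_effects(fit, c(-1, 1))
  # analytic: (a1 + a3 w)(b1 + b2 w) difference = 2 a3 b1 = 0.16
  expect_lt(abs(eff$indirect[2] - eff$indirect[1] - 2 * 0.2 * 0.4), 0.025)
})

test_that("simulated datasets round-trip to plain text with the truth sidecar", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_participants = 120, n_snps = 10, seed = 4)
  sim <- simulate_views(cfg)
  write_sim_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("env.tsv", "symptoms.tsv", "brain.tsv", "covariates.tsv",
      "genotypes.tsv", "variants.tsv", "truth.json")))))
  back <- read_feature_table(file.path(dir, "symptoms.tsv"))
  expect_equal(back$values, sim$data$symptoms$values, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$planted_r), sim$truth$planted_r)
})
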