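test_that("spectral and dense EM-REML engines share the same fixed point", {
  cfg <- st_cfg(n_families = 8, offspring = 8, n_snps = 300, seed = 5)
  sim <- simulate_dataset(cfg)
  G <- blend_relmat(build_G(sim$genotypes), 0.01)
  spec <- model_spec("HT", list(additive = G), "GBLUP-A")
  vfast <- fit_reml(spec, sim$phenotypes, tol = 1e-10, max_iter = 3000)

  ids <- G$ids
  y <- sim$phenotypes$value[match(ids, sim$phenotypes$id)]
  vd <- opbreed:::emreml_uni(y, matrix(1, length(ids), 1),
                             list(diag(length(ids))), list(G$values),
                             tol = 1e-10, max_iter = 3000)
  expect_equal(vfast$terms$additive[1, 1], vd$sigma2, tolerance = 1e-6)
  expect_equal(vfast$resid[[1]][1, 1], vd$sigma2_e, tolerance = 1e-6)
  expect_equal(tail(vfast$loglik, 1), tail(vd$loglik, 1), tolerance = 1e-8)
})

test_that("MME solution and PEV match a direct GLS oracle, parents included", {
  set.seed(31)
  n <- 9
  ids <- c(paste0("I", 1:8), "DAM")  # DAM carries no record
  L <- matrix(rnorm(n * n, 0, 0.3), n, n)
  K <- crossprod(L) + diag(n)
  K <- K / mean(diag(K))
  dimnames(K) <- list(ids, ids)
  Kr <- relmat(K, "G")
  phe <- phenotype_table(data.frame(id = paste0("I", 1:8),
                                    site = rep(c("S1", "S2"), each = 4),
                                    rep = "R1", trait = "HT",
                                    value = rnorm(8, 10, 2)))
  spec <- model_spec("HT", list(additive = Kr), "GBLUP-A")
  vc <- fit_reml(spec, phe, tol = 1e-9, max_iter = 2000)
  b <- predict_blup(spec, phe, vc)

  # dense oracle: GLS fixed effects, conditional-expectation BLUP and
  # conditional-variance PEV from the full covariance matrix
  Z <- matrix(0, 8, 2 * n); X <- matrix(0, 8, 2)
  keyof <- rep(1:2, each = 4)
  for (i in 1:8) {
    Z[i, (keyof[i] - 1) * n + i] <- 1
    X[i, keyof[i]] <- 1
  }
  Gcov <- kronecker(vc$terms$additive, K)
  Rv <- diag(c(rep(vc$resid$S1[1, 1], 4), rep(vc$resid$S2[1, 1], 4)))
  V <- Z %*% Gcov %*% t(Z) + Rv
  Vi <- solve(V)
  y <- phe$value
  bet <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- Gcov %*% t(Z) %*% Vi %*% (y - X %*% bet)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  PEV <- diag(Gcov - Gcov %*% t(Z) %*% P %*% Z %*% Gcov)
  expect_lt(max(abs(b$bv - as.numeric(u))), 1e-8)
  expect_lt(max(abs(b$pev - PEV)), 1e-8)
})

test_that("breeding values from a centered genomic matrix sum to about zero", {
  cfg <- st_cfg(n_families = 10, offspring = 8, n_snps = 400, seed = 53)
  sim <- simulate_dataset(cfg)
  G <- blend_relmat(build_G(sim$genotypes), 0.01)
  f <- fit_genetic_model(sim$phenotypes, list(additive = G), "HT",
                         tol = 1e-7)
  expect_lt(abs(sum(f$bvs$bv)) / stats::sd(f$bvs$bv), 0.05 * nrow(f$bvs))
})

test_that("EM-REML matches the balanced half-sib ANOVA estimator", {
  cfg <- st_cfg(n_families = 30, offspring = 12, n_snps = 100, h2 = 0.4,
                proportions = c(self = 0, full_sib = 0, half_sib = 1),
                seed = 17, rep_effect_sd = 0, n_qtl_per_trait = 50)
  sim <- simulate_dataset(cfg)
  A <- build_A(sim$pedigree_recorded)
  v <- fit_reml(model_spec("HT", list(additive = A), "ABLUP"),
                sim$phenotypes, tol = 1e-12, max_iter = 20000)
  phe <- sim$phenotypes
  fam <- sim$family[phe$id]
  k <- 12; s <- 30
  fm <- tapply(phe$value, fam, mean)
  MSB <- k * sum((fm - mean(phe$value))^2) / (s - 1)
  MSW <- sum((phe$value - fm[fam])^2) / (s * (k - 1))
  sa_anova <- 4 * (MSB - MSW) / k
  se_anova <- MSW - 0.75 * sa_anova
  expect_equal(v$terms$additive[1, 1], sa_anova, tolerance = 1e-3)
  expect_equal(v$resid[[1]][1, 1], se_anova, tolerance = 1e-3)
  # likelihood is non-decreasing along EM
  expect_true(all(diff(v$loglik) > -1e-6))
})

test_that("null data drive the genetic variance to the boundary", {
  cfg <- st_cfg(n_families = 25, offspring = 20, n_snps = 600, h2 = 0,
                seed = 19)
  sim <- simulate_dataset(cfg)
  G <- blend_relmat(build_G(sim$genotypes), 0.01)
  v <- fit_reml(model_spec("HT", list(additive = G), "GBLUP-A"),
                sim$phenotypes, tol = 1e-8)
  expect_lte(heritability(v)$h2, 0.05)
})

test_that("near-zero genetic variance gives near-zero breeding values", {
  cfg <- st_cfg(n_families = 5, offspring = 6, n_snps = 100, seed = 23)
  sim <- simulate_dataset(cfg)
  G <- blend_relmat(build_G(sim$genotypes), 0.01)
  spec <- model_spec("HT", list(additive = G), "GBLUP-A")
  vc <- fit_reml(spec, sim$phenotypes, tol = 1e-6)
  vc$terms$additive[1, 1] <- 1e-10
  b <- predict_blup(spec, sim$phenotypes, vc)
  expect_lt(max(abs(b$bv)), 1e-6)
})

test_that("shrinkage matches the closed form for two individuals and K = I", {
  # with A = I and one record each, BV_i = (y_i - mean) / (1 + lambda)
  ids <- c("a", "b")
  K <- as_relmat(diag(2), ids = ids)
  phe <- phenotype_table(data.frame(id = ids, site = "S1", rep = "R1",
                                    trait = "HT", value = c(8, 12)))
  spec <- model_spec("HT", list(additive = K), "GBLUP-A")
  vc <- manual_varcomp(list(additive = 2), resid = 1, traits = "HT",
                       sites = "S1")
  b <- predict_blup(spec, phe, vc)
  lambda <- 1 / 2
  expect_equal(b$bv, (c(8, 12) - 10) / (1 + lambda), tolerance = 1e-10)
})

test_that("the relationship-matrix abstraction is sound (A = I vs G = I)", {
  set.seed(41)
  ids <- paste0("i", 1:12)
  phe <- phenotype_table(data.frame(id = ids, site = "S1", rep = "R1",
                                    trait = "HT", value = rnorm(12, 10)))
  KA <- as_relmat(diag(12), kind = "A", ids = ids)
  KG <- as_relmat(diag(12), kind = "G", ids = ids)
  fa <- fit_genetic_model(phe, list(additive = KA), "HT", label = "ABLUP",
                          tol = 1e-10)
  fg <- fit_genetic_model(phe, list(additive = KG), "HT", label = "GBLUP-A",
                          tol = 1e-10)
  expect_equal(fa$varcomp$terms$additive, fg$varcomp$terms$additive,
               tolerance = 1e-10)
  expect_equal(fa$bvs$bv, fg$bvs$bv, tolerance = 1e-10)
  expect_equal(fa$bvs$pev, fg$bvs$pev, tolerance = 1e-10)
})

test_that("multi-trait fit recovers the negative growth/wood-density correlation", {
  cfg <- sim_config(n_families = 12, offspring_per_family_per_site = 5,
                    n_sites = 3, n_snps = 500, seed = 11)
  sim <- simulate_dataset(cfg)
  G <- blend_relmat(build_G(sim$genotypes), 0.01)
  spec <- model_spec(c("HT", "DBH", "WD"), list(additive = G), "GBLUP-ALL")
  v <- fit_reml(spec, sim$phenotypes, tol = 1e-4, max_iter = 80)
  expect_equal(nrow(v$keys), 9L)  # 3 traits x 3 sites
  expect_true(all(diff(v$loglik) > -1e-6))
  S <- v$terms$additive
  r <- S["WD@S1", "HT@S1"] / sqrt(S["WD@S1", "WD@S1"] * S["HT@S1", "HT@S1"])
  expect_lt(r, 0)  # negative genetic correlation, as simulated
  b <- predict_blup(spec, sim$phenotypes, v)
  expect_equal(nrow(b), 9L * length(G$ids))
})

test_that("stage-one adjustment removes block effects and nothing else", {
  # single replication: identity with a warning
  phe1 <- phenotype_table(data.frame(id = paste0("i", 1:4), site = "S1",
                                     rep = "R1", trait = "HT",
                                     value = c(1, 2, 3, 4)))
  ped1 <- pedigree_table(paste0("i", 1:4), rep(NA_character_, 4),
                         rep(NA_character_, 4))
  expect_warning(adj1 <- adjust_stage1(phe1, ped1), "single replication")
  expect_equal(adj1$value, phe1$value)

  # balanced two-replication toy: predictions equal the GLS oracle
  cfg <- st_cfg(n_families = 6, offspring = 6, n_snps = 50,
                n_reps_per_site = 2, rep_effect_sd = 1, seed = 29)
  sim <- simulate_dataset(cfg)
  ped <- sim$pedigree_recorded
  A <- build_A(ped)
  phe <- sim$phenotypes
  adj <- adjust_stage1(phe, ped, tol = 1e-10, max_iter = 5000)
  # oracle: refit the same two-variance model, then form the rep BLUP by a
  # direct dense V-inverse solve
  ids <- A$ids
  reps <- sort(unique(phe$rep))
  Zr <- outer(phe$rep, reps, "==") * 1
  Zg <- matrix(0, nrow(phe), length(ids))
  Zg[cbind(seq_len(nrow(phe)), match(phe$id, ids))] <- 1
  fit <- opbreed:::emreml_uni(phe$value, matrix(1, nrow(phe), 1),
                              list(Zr, Zg), list(NULL, A$values),
                              tol = 1e-10, max_iter = 5000)
  V <- fit$sigma2[1] * tcrossprod(Zr) +
    fit$sigma2[2] * Zg %*% A$values %*% t(Zg) +
    fit$sigma2_e * diag(nrow(phe))
  X <- matrix(1, nrow(phe), 1)
  Vi <- solve(V)
  bet <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% phe$value)
  u_rep <- fit$sigma2[1] * t(Zr) %*% Vi %*% (phe$value - X %*% bet)
  expect_equal(unname(fit$u[[1]]), unname(as.numeric(u_rep)),
               tolerance = 1e-6)
  expect_equal(adj$value, phe$value - as.numeric(Zr %*% fit$u[[1]]),
               tolerance = 1e-6)
})

test_that("prediction accuracy rises with heritability", {
  cors <- vapply(c(0.1, 0.3, 0.5, 0.7), function(h2) {
    cfg <- st_cfg(n_families = 15, offspring = 10, n_snps = 500, h2 = h2,
                  seed = 37)
    sim <- simulate_dataset(cfg)
    G <- blend_relmat(build_G(sim$genotypes), 0.01)
    f <- fit_genetic_model(sim$phenotypes, list(additive = G), "HT",
                           tol = 1e-6)
    b <- f$bvs[match(rownames(sim$true_bv), f$bvs$id), ]
    cor(sim$true_bv[, 1, 1], b$bv)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})
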