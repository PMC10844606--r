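test_that("heritability formulas reproduce their analytic cases", {
  vc <- manual_varcomp(list(additive = 1), resid = 1, traits = "HT",
                       sites = "S1")
  expect_equal(heritability(vc)$h2, 0.5)

  # additive + dominance + epistatic denominators
  vc_ade <- manual_varcomp(list(additive = 1, dominance = 0.5,
                                epistatic = 0.5),
                           resid = 2, traits = "HT", sites = "S1")
  expect_equal(heritability(vc_ade)$h2, 0.25)

  # site averaging: variances 1 and 3 across two sites, residual 1
  vc2 <- manual_varcomp(list(additive = c(1, 3)), resid = 1, traits = "HT",
                        sites = c("S1", "S2"))
  expect_equal(heritability(vc2)$h2, 2 / 3)
})

test_that("theoretical accuracy follows sqrt(1 - PEV/sigma2a) with clamping", {
  vc <- manual_varcomp(list(additive = 1), resid = 1, traits = "HT",
                       sites = "S1")
  mk_bvs <- function(pev) {
    b <- data.frame(id = paste0("i", seq_along(pev)), trait = "HT",
                    site = "S1", bv = 0, pev = pev)
    class(b) <- c("breeding_values", "data.frame")
    b
  }
  expect_equal(theoretical_accuracy(mk_bvs(0), vc)$ta, 1)
  expect_equal(theoretical_accuracy(mk_bvs(1), vc)$ta, 0)
  expect_equal(theoretical_accuracy(mk_bvs(0.36), vc)$ta, 0.8)
  expect_warning(ta <- theoretical_accuracy(mk_bvs(1.44), vc)$ta, "clamped")
  expect_equal(ta, 0)
})

test_that("expected gain is the top-n mean as a percentage of the trait mean", {
  b <- data.frame(id = paste0("i", 1:4), trait = "HT", site = "S1",
                  bv = c(3, 2, 1, 0), pev = 0)
  class(b) <- c("breeding_values", "data.frame")
  expect_equal(expected_gain(b, "HT", 2, 10), 25)
  b0 <- b; b0$bv <- 0
  expect_equal(expected_gain(b0, "HT", 2, 10), 0)
  expect_error(expected_gain(b, "DBH", 2, 10), "absent")
  # site averaging happens before ranking
  b2 <- rbind(b, within(b, {site <- "S2"; bv <- rev(bv)}))
  class(b2) <- c("breeding_values", "data.frame")
  expect_equal(expected_gain(b2, "HT", 4, 10), 15)
})

test_that("group co-ancestry matches its closed forms", {
  K1 <- as_relmat(matrix(1, 1, 1), ids = "x")
  expect_equal(group_coancestry(c(x = 1), K1)$group, 0.5)
  K2 <- as_relmat(diag(2), ids = c("x", "y"))
  expect_equal(group_coancestry(c(x = 0.5, y = 0.5), K2)$group, 0.25)
  for (N in c(3, 7, 12)) {
    K <- as_relmat(diag(N))
    cc <- setNames(rep(1 / N, N), K$ids)
    expect_equal(group_coancestry(cc, K)$group, 1 / (2 * N))
    expect_equal(group_coancestry(cc, K)$mean_pairwise, 0)
  }
  expect_error(group_coancestry(c(x = 0.7, y = 0.7), K2), "sum to 1")
})

test_that("OCS reproduces its small worked examples", {
  bm <- matrix(c(4, 3, 2, 1), 4, 1, dimnames = list(paste0("T", 1:4), "HT"))
  K <- as_relmat(diag(4), ids = paste0("T", 1:4))
  s <- ocs_optimize(bm, K, ocs_config(n_max = 2), "HT")
  expect_setequal(s$selected, c("T1", "T2"))
  expect_equal(unname(s$gain["HT"]), 3.5)
  expect_true(s$optimal)

  # forbidding related pairs forces {T1, T3}
  m2 <- diag(4); m2[1, 2] <- m2[2, 1] <- 0.5
  K2 <- as_relmat(m2, ids = paste0("T", 1:4))
  s2 <- ocs_optimize(bm, K2, ocs_config(n_max = 2, delta_f_limit = 0), "HT")
  expect_setequal(s2$selected, c("T1", "T3"))
  expect_equal(unname(s2$gain["HT"]), 3.0)

  # verify against exhaustive enumeration over all subsets of size <= 2
  combos <- c(lapply(1:4, function(i) i),
              combn(4, 2, simplify = FALSE))
  feas_gain <- vapply(combos, function(ix) {
    mp <- if (length(ix) > 1) mean(m2[ix, ix][upper.tri(m2[ix, ix])]) else 0
    if (mp > 0) -Inf else sum(bm[ix, 1])
  }, numeric(1))
  expect_equal(s2$objective, max(feas_gain))

  # infeasibility is reported explicitly
  s3 <- ocs_optimize(bm, K,
                     ocs_config(n_max = 2,
                                constraints = list(list(trait = "HT",
                                                        dir = ">=",
                                                        bound = 99))),
                     "HT")
  expect_false(s3$feasible)
})

test_that("heuristic OCS matches the exact optimum and never beats it", {
  set.seed(9)
  agree <- 0; total <- 0
  for (r in 1:20) {
    n <- 15
    L <- matrix(rnorm(n * n, 0, 0.3), n, n)
    K <- crossprod(L) / 2 + diag(n) * 0.5
    K <- as_relmat(K / mean(diag(K)))
    bv <- matrix(rnorm(n), n, 1, dimnames = list(K$ids, "HT"))
    cfgE <- ocs_config(n_max = 6, delta_f_limit = 0.15, seed = r)
    cfgH <- ocs_config(n_max = 6, delta_f_limit = 0.15, exact_limit = 0,
                       restarts = 30, seed = r)
    se <- ocs_optimize(bv, K, cfgE, "HT")
    sh <- ocs_optimize(bv, K, cfgH, "HT")
    if (se$feasible && sh$feasible) {
      total <- total + 1
      expect_lte(sh$objective, se$objective + 1e-9)
      if (abs(sh$objective - se$objective) < 1e-9) agree <- agree + 1
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("relaxing the co-ancestry limit never decreases the gain", {
  cfg <- st_cfg(n_families = 10, offspring = 8, n_snps = 400, seed = 43)
  sim <- simulate_dataset(cfg)
  G <- blend_relmat(build_G(sim$genotypes), 0.01)
  f <- fit_genetic_model(sim$phenotypes, list(additive = G), "HT",
                         tol = 1e-6)
  objs <- vapply(list(0.125, 0.25, NULL), function(df) {
    s <- ocs_optimize(f$bvs, G, ocs_config(n_max = 10, delta_f_limit = df,
                                           exact_limit = 0, restarts = 20),
                      "HT")
    if (s$feasible) s$objective else -Inf
  }, numeric(1))
  expect_true(all(diff(objs) >= -1e-9))
  # unconstrained OCS equals truncation selection on the objective
  s_un <- ocs_optimize(f$bvs, G, ocs_config(n_max = 10, exact_limit = 0,
                                            restarts = 5), "HT")
  top <- names(sort(tapply(f$bvs$bv[f$bvs$trait == "HT"],
                           f$bvs$id[f$bvs$trait == "HT"], mean),
                    decreasing = TRUE))[1:10]
  expect_setequal(s_un$selected, top)
})

test_that("co-ancestry constraints spread selections across more families", {
  cfg <- st_cfg(n_families = 12, offspring = 10, n_snps = 600, seed = 47,
                proportions = c(self = 0, full_sib = 0.5, half_sib = 0.5))
  sim <- simulate_dataset(cfg)
  G <- blend_relmat(build_G(sim$genotypes), 0.01)
  f <- fit_genetic_model(sim$phenotypes, list(additive = G), "HT",
                         tol = 1e-6)
  pick <- function(df) {
    s <- ocs_optimize(f$bvs, G, ocs_config(n_max = 12, delta_f_limit = df,
                                           exact_limit = 0, restarts = 20),
                      "HT")
    length(unique(sim$family[s$selected]))
  }
  expect_gte(pick(0.1), pick(NULL))
  # constrained wood-density mean stays at or above the base population
  cfg3 <- sim_config(n_families = 10, offspring_per_family_per_site = 8,
                     n_sites = 1, n_snps = 500, seed = 49)
  sim3 <- simulate_dataset(cfg3)
  G3 <- blend_relmat(build_G(sim3$genotypes), 0.01)
  spec3 <- model_spec(c("HT", "DBH", "WD"), list(additive = G3), "GBLUP-ALL")
  v3 <- fit_reml(spec3, sim3$phenotypes, tol = 1e-4, max_iter = 40)
  b3 <- predict_blup(spec3, sim3$phenotypes, v3)
  s3 <- ocs_optimize(b3, G3,
                     ocs_config(n_max = 10, exact_limit = 0, restarts = 20,
                                constraints = list(list(trait = "WD",
                                                        dir = ">=",
                                                        bound = 0))),
                     objective_traits = c("HT", "DBH"))
  expect_true(s3$feasible)
  expect_gte(unname(s3$gain["WD"]), 0)
})
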