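test_that("A matrix matches textbook cases", {
  # founders only -> identity
  ped <- pedigree_table(c("F1", "F2"), c(NA, NA), c(NA, NA))
  expect_equal(build_A(ped)$values, diag(2), ignore_attr = TRUE)

  # two half-sibs through a shared dam
  ped <- pedigree_table(c("F1", "O1", "O2"), c(NA, "F1", "F1"),
                        c(NA, NA, NA))
  A <- build_A(ped)$values
  expect_equal(A["O1", "O2"], 0.25)
  expect_equal(diag(A), c(1, 1, 1), ignore_attr = TRUE)

  # selfing: dam = sire -> F = 0.5
  ped <- pedigree_table(c("F1", "O1"), c(NA, "F1"), c(NA, "F1"))
  A <- build_A(ped)$values
  expect_equal(A["O1", "O1"], 1.5)
  expect_equal(A["F1", "O1"], 1.0)
})

test_that("A matrix equals the recursive kinship oracle on random pedigrees", {
  for (seed in 1:25) {
    ped <- random_pedigree(sample(5:30, 1), seed = seed)
    expect_equal(build_A(ped)$values, kinship_oracle(ped), tolerance = 1e-12)
  }
})

test_that("mean imputation fills column means and leaves frequencies intact", {
  g <- genotype_matrix(cbind(s1 = c(0, NA, 2), s2 = c(1, NA, NA, 2)[1:3],
                             s3 = c(0, 1, 2)),
                       ids = c("a", "b", "c"))
  gi <- impute_and_freq(g)
  expect_equal(gi$codes[2, "s1"], 1.0)
  expect_true(gi$imputed)
  expect_equal(gi$p, g$p)

  g2 <- genotype_matrix(cbind(s1 = c(1, NA, NA, 2)), ids = letters[1:4])
  expect_equal(unname(impute_and_freq(g2)$codes[2:3, 1]), c(1.5, 1.5))

  # no missing entries: identity transform
  g3 <- genotype_matrix(cbind(s1 = c(0, 1, 2)), ids = letters[1:3])
  expect_equal(impute_and_freq(g3)$codes, g3$codes)

  expect_error(genotype_matrix(cbind(s1 = c(NA_real_, NA_real_)),
                               ids = c("a", "b")), "all entries missing")
})

test_that("G, D and their Hadamard product match hand-derived matrices", {
  g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1,
                              dimnames = list(c("a", "b", "c"), "s1")),
                       imputed = TRUE)
  G <- build_G(g)
  expect_equal(unname(G$values),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3))
  expect_equal(G$scale, 0.5)
  D <- build_D(g)
  expect_equal(unname(D$values),
               matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3))
  EPI <- build_epistatic(G, D)
  expect_equal(unname(EPI$values),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3))
  expect_equal(EPI$kind, "EPI")
  # Hadamard product commutes
  expect_equal(build_epistatic(D, G)$values, EPI$values)
})

test_that("G is invariant to column duplication, row order and allele flips", {
  set.seed(3)
  codes <- matrix(rbinom(60, 2, 0.4), 10, 6,
                  dimnames = list(paste0("i", 1:10), paste0("s", 1:6)))
  g <- genotype_matrix(codes, imputed = TRUE)
  G <- build_G(g)$values
  # duplicating every SNP leaves G unchanged
  g2 <- genotype_matrix(cbind(codes, codes),
                        ids = rownames(codes),
                        snp_ids = paste0("s", 1:12), imputed = TRUE)
  expect_equal(build_G(g2)$values, G, ignore_attr = TRUE)
  # permutation equivariance
  perm <- sample(10)
  Gp <- build_G(genotype_matrix(codes[perm, ], imputed = TRUE))$values
  expect_equal(Gp, G[perm, perm])
  # flipping 0 <-> 2 with recomputed frequencies
  Gf <- build_G(genotype_matrix(2 - codes, ids = rownames(codes),
                                snp_ids = colnames(codes),
                                imputed = TRUE))$values
  expect_equal(Gf, G, tolerance = 1e-12)
  # identical individuals give identical rows, G(i,i) = G(i,j)
  g3 <- genotype_matrix(codes[c(1, 1, 2:10), ],
                        ids = c("i1", "i1b", paste0("i", 2:10)),
                        snp_ids = colnames(codes), imputed = TRUE)
  G3 <- build_G(g3)$values
  expect_equal(G3["i1", "i1"], G3["i1", "i1b"])

  # all-monomorphic input is an error
  mono <- genotype_matrix(matrix(2, 3, 2, dimnames = list(letters[1:3],
                                                          c("s1", "s2"))),
                          imputed = TRUE)
  expect_error(build_G(mono), "monomorphic")
})

test_that("blending records its weight and restores invertibility", {
  set.seed(4)
  codes <- matrix(rbinom(40, 2, 0.5), 10, 4,
                  dimnames = list(paste0("i", 1:10), paste0("s", 1:4)))
  G <- build_G(genotype_matrix(codes, imputed = TRUE))
  expect_error(solve(G$values), "singular")
  Gb <- blend_relmat(G, 0.02)
  expect_equal(Gb$blend, 0.02)
  expect_no_error(solve(Gb$values))
  expect_equal(Gb$values, 0.98 * G$values + 0.02 * diag(10),
               ignore_attr = TRUE)
})

test_that("genomic pedigree verification recovers injected mislabels", {
  cfg <- st_cfg(n_families = 20, offspring = 10, n_snps = 1000,
                pedigree_error_rate = 0.05, seed = 21)
  gp <- simulate_pedigree_genotypes(cfg)
  altered <- attr(gp$pedigree_recorded, "altered")
  expect_gt(length(altered), 0)
  qc <- verify_pedigree(build_G(gp$genotypes), gp$pedigree_recorded)
  found <- intersect(qc$reassigned$id, altered)
  expect_gte(length(found), ceiling(0.9 * length(altered)))
  # reassignments point to the true family
  truefam <- gp$pedigree_true$dam[match(found, gp$pedigree_true$id)]
  hit <- qc$reassigned$new_family[match(found, qc$reassigned$id)] == truefam
  expect_gte(mean(hit), 0.9)

  # clean data -> empty report
  cfg0 <- st_cfg(n_families = 10, offspring = 10, n_snps = 1000,
                 proportions = c(self = 0, full_sib = 0, half_sib = 1),
                 seed = 3)
  gp0 <- simulate_pedigree_genotypes(cfg0)
  qc0 <- verify_pedigree(build_G(gp0$genotypes), gp0$pedigree_recorded)
  expect_length(qc0$removed_low_diagonal, 0L)
  expect_equal(nrow(qc0$reassigned), 0L)
  expect_length(qc0$unassigned, 0L)
  expect_setequal(qc0$final_ids, gp0$genotypes$ids)
})

test_that("kinship networks honour the threshold and partition the nodes", {
  K <- as_relmat(matrix(c(1, 0.06, 0.06, 1), 2), ids = c("a", "b"))
  n1 <- network_edges(K, 0.05)
  expect_equal(nrow(n1$edges), 1L)
  expect_length(n1$components, 1L)
  n2 <- network_edges(K, 0.10)
  expect_equal(nrow(n2$edges), 0L)
  expect_length(n2$components, 2L)

  # edge count is non-increasing in the threshold; singletons above max
  set.seed(8)
  M <- crossprod(matrix(rnorm(49, 0, 0.4), 7)) + diag(7) * 0.3
  K2 <- as_relmat(M / mean(diag(M)))
  ths <- c(0, 0.05, 0.1, 0.2, 0.5, 1)
  counts <- vapply(ths, function(t) nrow(network_edges(K2, t)$edges),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  off <- K2$values[upper.tri(K2$values)]
  nbig <- network_edges(K2, max(off) + 0.01)
  expect_length(nbig$components, 7L)

  # half-sib families at 0.05 resolve into family components on A
  cfg <- st_cfg(n_families = 6, offspring = 8, n_snps = 50,
                proportions = c(self = 0, full_sib = 0, half_sib = 1),
                seed = 5)
  gp <- simulate_pedigree_genotypes(cfg)
  A <- build_A(gp$pedigree_recorded)
  off_ids <- gp$genotypes$ids
  Asub <- relmat(A$values[off_ids, off_ids], kind = "A")
  net <- network_edges(Asub, 0.05)
  expect_length(net$components, 6L)
  for (comp in net$components) {
    expect_length(unique(gp$family[comp]), 1L)
  }
})
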