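#' Configuration for the open-pollinated progeny-test simulator
#'
#' Defaults emulate a spruce-like OP progeny test: ~25 OP families of mixed
#' sibship (selfs / full-sibs / half-sibs), three sites with randomized
#' complete blocks, traits HT (m), DBH (cm) and WD (g/cm3) with moderate
#' heritabilities and negative genetic correlations of wood density with the
#' growth traits.
#'
#' @param n_families number of OP families (seed donors)
#' @param offspring_per_family_per_site offspring per family at each site
#' @param n_sites number of test sites
#' @param n_reps_per_site randomized blocks (replications) per site
#' @param n_snps number of unlinked biallelic SNPs
#' @param founder_maf_range uniform range the founder alternate-allele
#'   frequencies are drawn from
#' @param mating_proportions named numeric (self, full_sib, half_sib)
#'   summing to 1: sibship mixture within each OP family
#' @param n_qtl_per_trait number of causal SNPs (a common causal set is
#'   shared by all traits so that genetic correlations can arise)
#' @param target_h2 named per-trait narrow-sense heritability in \[0, 1)
#' @param genetic_correlations trait x trait correlation matrix (unit
#'   diagonal, positive definite)
#' @param additive_sd named per-trait additive genetic standard deviation in
#'   trait units
#' @param trait_means named per-trait population means (used for percentage
#'   gains)
#' @param cross_site_cor genetic correlation of an individual's site-specific
#'   breeding values across sites (genotype-by-environment)
#' @param site_effect_sd,rep_effect_sd standard deviations of fixed site
#'   shifts and block effects, as multiples of each trait's additive SD
#' @param pedigree_error_rate fraction of offspring whose recorded dam is
#'   mislabelled
#' @param seed integer seed; all simulator randomness derives from it
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_families = 25,
                       offspring_per_family_per_site = 15,
                       n_sites = 3,
                       n_reps_per_site = 4,
                       n_snps = 2000,
                       founder_maf_range = c(0.05, 0.5),
                       mating_proportions = c(self = 0.05, full_sib = 0.25,
                                              half_sib = 0.70),
                       n_qtl_per_trait = 200,
                       target_h2 = c(HT = 0.6, DBH = 0.4, WD = 0.5),
                       genetic_correlations = NULL,
                       additive_sd = c(HT = 1.5, DBH = 2.5, WD = 0.04),
                       trait_means = c(HT = 15, DBH = 20, WD = 0.45),
                       cross_site_cor = 0.8,
                       site_effect_sd = 1.0,
                       rep_effect_sd = 0.5,
                       pedigree_error_rate = 0,
                       seed = 1L) {
  traits <- names(target_h2)
  if (is.null(traits)) stop("target_h2 must be a named vector of traits")
  if (is.null(genetic_correlations)) {
    genetic_correlations <- diag(length(traits))
    dimnames(genetic_correlations) <- list(traits, traits)
    if (all(c("HT", "DBH", "WD") %in% traits)) {
      genetic_correlations["HT", "DBH"] <- genetic_correlations["DBH", "HT"] <- 0.5
      genetic_correlations["WD", "HT"] <- genetic_correlations["HT", "WD"] <- -0.53
      genetic_correlations["WD", "DBH"] <- genetic_correlations["DBH", "WD"] <- -0.72
    }
  }
  cfg <- list(n_families = as.integer(n_families),
              offspring_per_family_per_site = as.integer(offspring_per_family_per_site),
              n_sites = as.integer(n_sites),
              n_reps_per_site = as.integer(n_reps_per_site),
              n_snps = as.integer(n_snps),
              founder_maf_range = founder_maf_range,
              mating_proportions = mating_proportions,
              n_qtl_per_trait = as.integer(n_qtl_per_trait),
              target_h2 = target_h2,
              genetic_correlations = genetic_correlations,
              additive_sd = additive_sd[traits],
              trait_means = trait_means[traits],
              cross_site_cor = cross_site_cor,
              site_effect_sd = site_effect_sd,
              rep_effect_sd = rep_effect_sd,
              pedigree_error_rate = pedigree_error_rate,
              seed = as.integer(seed),
              traits = traits)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  mp <- cfg$mating_proportions
  if (!all(c("self", "full_sib", "half_sib") %in% names(mp)))
    stop("mating_proportions must be named (self, full_sib, half_sib)")
  if (abs(sum(mp) - 1) > 1e-12) stop("mating_proportions must sum to 1")
  if (any(mp < 0)) stop("mating_proportions must be non-negative")
  with(cfg, {
    if (any(c(n_families, offspring_per_family_per_site, n_sites,
              n_reps_per_site, n_snps) < 1L))
      stop("all counts in the simulation config must be positive")
    if (n_qtl_per_trait > n_snps) stop("n_qtl_per_trait exceeds n_snps")
    if (any(target_h2 < 0 | target_h2 >= 1)) stop("target_h2 must lie in [0, 1)")
    if (pedigree_error_rate < 0 || pedigree_error_rate > 1)
      stop("pedigree_error_rate must lie in [0, 1]")
    if (founder_maf_range[1] <= 0 || founder_maf_range[2] > 0.5 ||
        founder_maf_range[1] > founder_maf_range[2])
      stop("founder_maf_range must satisfy 0 < low <= high <= 0.5")
  })
  R <- cfg$genetic_correlations
  if (any(abs(diag(R) - 1) > 1e-12) || max(abs(R - t(R))) > 1e-12)
    stop("genetic_correlations must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("genetic_correlations must be positive definite")
  invisible(cfg)
}

# run expr with a private RNG stream, restoring the caller's state
with_sim_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# one gamete per (individual, SNP): for unlinked loci a parent with dosage g
# transmits the alternate allele with probability g/2 (deterministic for
# homozygotes, fair coin for heterozygotes)
draw_gametes <- function(parent_codes) {
  p <- parent_codes / 2
  matrix(rbinom(length(p), 1L, p), nrow = nrow(parent_codes))
}

#' Simulate an OP pedigree and genotypes by gene dropping
#'
#' Founder genotypes (seed donors and pollen donors) are drawn per SNP under
#' Hardy-Weinberg at frequencies uniform on the configured range. Each
#' offspring receives one gamete from its dam and one from a sire chosen by
#' the sibship mixture: the dam itself (self), a single shared within-family
#' pollen father (full-sib), or a fresh father from an effectively infinite
#' unrelated pollen pool (half-sib). The true pedigree records all sires;
#' the recorded pedigree lists every sire as unknown, as in OP testing.
#'
#' @param config a [sim_config()]
#' @return list with `pedigree_true`, `pedigree_recorded` (both
#'   [pedigree_table()]; the recorded one only covers dams and offspring),
#'   `genotypes` (offspring [genotype_matrix()]), `dam_genotypes` (the seed
#'   donors, a founder sample) and `family` (named vector mapping offspring
#'   id to recorded dam)
#' @export
simulate_pedigree_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_sim_rng(cfg$seed, {
    nf <- cfg$n_families
    noff_fam <- cfg$offspring_per_family_per_site * cfg$n_sites
    m <- cfg$n_snps
    p0 <- runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
    # Hardy-Weinberg draws, one column (SNP) at a time
    hw <- function(k) {
      g <- matrix(0L, k, m)
      for (j in seq_len(m)) g[, j] <- rbinom(k, 2L, p0[j])
      g
    }
    dams <- paste0("DAM", sprintf("%03d", seq_len(nf)))
    dam_geno <- hw(nf)
    fs_fathers <- paste0("FSF", sprintf("%03d", seq_len(nf)))
    fsf_geno <- hw(nf)

    off_id <- character(0); off_dam <- character(0); off_sire <- character(0)
    off_codes <- matrix(0L, nf * noff_fam, m)
    hs_count <- 0L
    hs_ids <- character(0); hs_geno <- NULL
    row <- 0L
    mp <- cfg$mating_proportions
    for (f in seq_len(nf)) {
      types <- sample(c("self", "full_sib", "half_sib"), noff_fam,
                      replace = TRUE, prob = mp)
      n_hs <- sum(types == "half_sib")
      pool <- if (n_hs) hw(n_hs) else NULL
      pool_ids <- if (n_hs) paste0("HSP", sprintf("%05d", hs_count + seq_len(n_hs))) else character(0)
      hs_count <- hs_count + n_hs
      hs_ids <- c(hs_ids, pool_ids)
      if (n_hs) hs_geno <- rbind(hs_geno, pool)
      k_hs <- 0L
      for (o in seq_len(noff_fam)) {
        row <- row + 1L
        dam_g <- dam_geno[f, , drop = FALSE]
        sire_lab <- switch(types[o],
                           self = dams[f],
                           full_sib = fs_fathers[f],
                           half_sib = { k_hs <- k_hs + 1L; pool_ids[k_hs] })
        sire_g <- switch(types[o],
                         self = dam_g,
                         full_sib = fsf_geno[f, , drop = FALSE],
                         half_sib = pool[k_hs, , drop = FALSE])
        off_codes[row, ] <- draw_gametes(dam_g) + draw_gametes(sire_g)
        off_id <- c(off_id, sprintf("F%02dO%03d", f, o))
        off_dam <- c(off_dam, dams[f])
        off_sire <- c(off_sire, sire_lab)
      }
    }
    founders_true <- c(dams, fs_fathers, hs_ids)
    ped_true <- pedigree_table(
      id = c(founders_true, off_id),
      dam = c(rep(NA_character_, length(founders_true)), off_dam),
      sire = c(rep(NA_character_, length(founders_true)), off_sire))
    ped_rec <- pedigree_table(
      id = c(dams, off_id),
      dam = c(rep(NA_character_, nf), off_dam),
      sire = rep(NA_character_, nf + length(off_id)))
    if (cfg$pedigree_error_rate > 0) {
      ped_rec <- inject_pedigree_errors(ped_rec, cfg$pedigree_error_rate,
                                        seed = cfg$seed + 1L)
    }
    snp_ids <- paste0("SNP", sprintf("%05d", seq_len(m)))
    rownames(off_codes) <- off_id
    colnames(off_codes) <- snp_ids
    geno <- genotype_matrix(off_codes, imputed = TRUE)
    fam <- setNames(ped_rec$dam[match(off_id, ped_rec$id)], off_id)
    dam_geno <- genotype_matrix(dam_geno, ids = dams, snp_ids = snp_ids,
                                imputed = TRUE)
    list(pedigree_true = ped_true, pedigree_recorded = ped_rec,
         genotypes = geno, dam_genotypes = dam_geno, family = fam)
  })
}

#' Simulate phenotypes with site, block and polygenic effects
#'
#' A common set of causal SNPs receives multivariate-normal effects across
#' all (trait, site) combinations, with covariance (trait correlation
#' matrix) x (compound-symmetric site correlation at `cross_site_cor`).
#' Effect vectors are rotated against the realized genotype covariance so
#' the sample covariance of breeding values matches the target exactly;
#' each trait's breeding values are then scaled to its additive SD, and the
#' residual SD is set from the target heritability. Offspring are assigned
#' to sites family-balanced and to blocks at random within site.
#'
#' @param config a [sim_config()]
#' @param genotypes offspring [genotype_matrix()] (complete)
#' @return list with `phenotypes` ([phenotype_table()]), `true_bv`
#'   (3-d array individual x trait x site, trait units), `site_of`
#'   (named site assignment), `qtl` (causal SNP ids) and `true_params`
#' @export
simulate_phenotypes <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  if (!genotypes$imputed) stop("genotypes must be complete")
  cfg <- config
  with_sim_rng(cfg$seed + 2L, {
    traits <- cfg$traits
    nt <- length(traits); ns <- cfg$n_sites
    ids <- genotypes$ids
    n <- length(ids)

    # family-balanced site assignment: within each family, consecutive
    # blocks of offspring go to sites 1..ns (matching the simulator's
    # per-family-per-site design)
    fam_of <- sub("O[0-9]+$", "", ids)
    site_of <- integer(n)
    for (f in unique(fam_of)) {
      idx <- which(fam_of == f)
      site_of[idx] <- rep(seq_len(ns), each = ceiling(length(idx) / ns),
                          length.out = length(idx))
    }
    names(site_of) <- ids

    # causal architecture: common QTL set, effects MVN across (trait, site)
    qtl <- sort(sample(which(!genotypes$monomorphic),
                       min(cfg$n_qtl_per_trait,
                           sum(!genotypes$monomorphic))))
    Wq <- genotypes$codes[, qtl, drop = FALSE]
    Cs <- matrix(cfg$cross_site_cor, ns, ns); diag(Cs) <- 1
    target <- kronecker(cfg$genetic_correlations, Cs)  # trait-major blocks
    B <- matrix(rnorm(length(qtl) * nt * ns), length(qtl), nt * ns)
    # rotate B so that the realized covariance of Wq %*% B equals `target`
    raw <- Wq %*% B
    S <- stats::cov(raw)
    B <- B %*% backsolve(chol(S), chol(target))
    BV <- Wq %*% B                      # n x (nt*ns), unit variance columns
    BV <- sweep(BV, 2, colMeans(BV))    # breeding values centred in-sample

    true_bv <- array(0, dim = c(n, nt, ns),
                     dimnames = list(ids, traits, paste0("S", seq_len(ns))))
    resid_sd <- numeric(nt); names(resid_sd) <- traits
    for (t in seq_len(nt)) {
      h2 <- cfg$target_h2[[traits[t]]]
      a_sd <- cfg$additive_sd[[traits[t]]]
      for (s in seq_len(ns)) {
        col <- (t - 1L) * ns + s
        true_bv[, t, s] <- if (h2 > 0) BV[, col] * a_sd else 0
      }
      resid_sd[t] <- if (h2 > 0) a_sd * sqrt((1 - h2) / h2) else 1
    }

    site_eff <- matrix(rnorm(ns * nt, 0, cfg$site_effect_sd), ns, nt)
    rep_of <- integer(n)
    rows <- list()
    for (s in seq_len(ns)) {
      at_s <- which(site_of == s)
      rep_of[at_s] <- sample(rep(seq_len(cfg$n_reps_per_site),
                                 length.out = length(at_s)))
    }
    rep_eff <- array(rnorm(ns * cfg$n_reps_per_site * nt, 0, cfg$rep_effect_sd),
                     dim = c(ns, cfg$n_reps_per_site, nt))
    for (t in seq_len(nt)) {
      a_sd <- cfg$additive_sd[[traits[t]]]
      e <- rnorm(n, 0, resid_sd[t])
      val <- cfg$trait_means[[traits[t]]] +
        a_sd * site_eff[site_of, t] +
        a_sd * rep_eff[cbind(site_of, rep_of, t)] +
        true_bv[cbind(seq_len(n), t, site_of)] + e
      rows[[t]] <- data.frame(id = ids, site = paste0("S", site_of),
                              rep = paste0("R", rep_of),
                              trait = traits[t], value = val,
                              stringsAsFactors = FALSE)
    }
    phe <- phenotype_table(do.call(rbind, rows), trait_list = traits)
    list(phenotypes = phe, true_bv = true_bv,
         site_of = setNames(paste0("S", site_of), ids),
         qtl = genotypes$snp_ids[qtl],
         true_params = list(target_h2 = cfg$target_h2,
                            genetic_correlations = cfg$genetic_correlations,
                            additive_sd = cfg$additive_sd,
                            resid_sd = resid_sd,
                            trait_means = cfg$trait_means))
  })
}

#' Inject dam-mislabelling errors into a recorded pedigree
#'
#' Each offspring (row with a known dam) independently has its recorded dam
#' replaced by a different random dam with probability `rate`, emulating the
#' labelling errors that accumulate through cone collection, seed handling
#' and planting.
#'
#' @param pedigree a [pedigree_table()]
#' @param rate per-offspring mislabelling probability in \[0, 1\]
#' @param seed integer seed
#' @return the altered [pedigree_table()]; attribute `"altered"` lists the
#'   mislabelled offspring ids
#' @export
inject_pedigree_errors <- function(pedigree, rate, seed = 1L) {
  stopifnot(inherits(pedigree, "pedigree_table"), rate >= 0, rate <= 1)
  off <- which(!is.na(pedigree$dam))
  dams <- unique(pedigree$dam[off])
  out <- pedigree
  altered <- character(0)
  if (rate > 0 && length(off) && length(dams) > 1L) {
    draw <- with_sim_rng(seed, {
      hit <- off[runif(length(off)) < rate]
      newdam <- vapply(hit, function(i) {
        pool <- setdiff(dams, pedigree$dam[i])
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      list(hit = hit, newdam = newdam)
    })
    out$dam[draw$hit] <- draw$newdam
    altered <- pedigree$id[draw$hit]
  }
  out <- pedigree_table(out$id, out$dam, out$sire)
  attr(out, "altered") <- altered
  out
}

#' Simulate a complete OP progeny-test dataset
#'
#' Convenience wrapper chaining [simulate_pedigree_genotypes()] and
#' [simulate_phenotypes()].
#'
#' @param config a [sim_config()]
#' @return list with `pedigree_true`, `pedigree_recorded`, `genotypes`,
#'   `phenotypes`, `true_bv`, `site_of`, `qtl`, `family`, `true_params`
#'   and the `config`
#' @export
simulate_dataset <- function(config) {
  gp <- simulate_pedigree_genotypes(config)
  ph <- simulate_phenotypes(config, gp$genotypes)
  c(gp, ph, list(config = config))
}
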