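# Shared fixtures and independent oracles used across the test files.

# single-trait simulator configuration shortcut
st_cfg <- function(n_families = 20, offspring = 10, n_sites = 1, n_snps = 500,
                   h2 = 0.5, proportions = c(self = 0.05, full_sib = 0.25,
                                             half_sib = 0.70),
                   seed = 1L, ...) {
  extra <- list(...)
  if (!"n_qtl_per_trait" %in% names(extra))
    extra$n_qtl_per_trait <- min(200L, max(5L, n_snps %/% 4L))
  do.call(sim_config,
          c(list(n_families = n_families,
                 offspring_per_family_per_site = offspring,
                 n_sites = n_sites, n_snps = n_snps,
                 mating_proportions = proportions,
                 target_h2 = c(HT = h2),
                 genetic_correlations = matrix(1, 1, 1,
                                               dimnames = list("HT", "HT")),
                 additive_sd = c(HT = 1), trait_means = c(HT = 15),
                 seed = seed),
            extra))
}

# recursive-definition kinship oracle: phi(i, j) = coefficient of kinship,
# A = 2 phi. Requires parents to precede offspring in row order (true for
# random_pedigree and the simulator's pedigrees).
kinship_oracle <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(d[i], s[i]))
    } else {
      a <- max(i, j); b <- min(i, j)  # recurse through the later individual
      0.5 * (phi(d[a], b) + phi(s[a], b))
    }
    memo[[key]] <- v
    v
  }
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# random valid pedigree: founders first, every later individual draws its
# parents (possibly unknown, possibly equal = selfing) from earlier ones
random_pedigree <- function(n, seed) {
  set.seed(seed)
  n_f <- max(2L, rbinom(1, n, 0.3))
  id <- sprintf("P%02d", seq_len(n))
  dam <- rep(NA_character_, n)
  sire <- rep(NA_character_, n)
  for (i in seq.int(n_f + 1L, n)) {
    pool <- id[seq_len(i - 1L)]
    if (runif(1) < 0.8) dam[i] <- sample(pool, 1L)
    if (runif(1) < 0.7) sire[i] <- if (!is.na(dam[i]) && runif(1) < 0.1)
      dam[i] else sample(pool, 1L)
  }
  pedigree_table(id, dam, sire)
}

# relmat from a plain matrix with generated ids
as_relmat <- function(m, kind = "G", ids = sprintf("C%02d", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  relmat(m, kind = kind)
}

# hand-assembled op_varcomp with one additive (or more) term, for testing
# the heritability / accuracy formulas in isolation
manual_varcomp <- function(terms, resid, traits, sites) {
  keys <- expand.grid(trait = traits, site = sites,
                      stringsAsFactors = FALSE)[, c("site", "trait")]
  keys <- keys[order(keys$site), ]
  keys$label <- paste0(keys$trait, "@", keys$site)
  q <- nrow(keys)
  terms <- lapply(terms, function(v) {
    S <- diag(rep(v, length.out = q), q)
    dimnames(S) <- list(keys$label, keys$label)
    S
  })
  resid_l <- lapply(sites, function(s) {
    R <- diag(rep(resid, length.out = length(traits)), length(traits))
    dimnames(R) <- list(traits, traits)
    R
  })
  names(resid_l) <- sites
  nm <- character(0); vals <- numeric(0)
  for (t in seq_along(terms)) {
    for (k in seq_len(q)) for (l in seq_len(k)) {
      nm <- c(nm, sprintf("Sg%d.%s:%s", t, keys$label[k], keys$label[l]))
      vals <- c(vals, terms[[t]][k, l])
    }
  }
  for (s in sites) for (i in seq_along(traits)) for (j in seq_len(i)) {
    nm <- c(nm, sprintf("R.%s.%s:%s", s, traits[i], traits[j]))
    vals <- c(vals, resid_l[[s]][i, j])
  }
  vc <- diag(1e-4, length(nm)); dimnames(vc) <- list(nm, nm)
  structure(list(terms = terms, resid = resid_l, keys = keys,
                 traits = traits, sites = sites,
                 params = setNames(vals, nm), se = sqrt(diag(vc)),
                 vcov_params = vc, loglik = 0, converged = TRUE,
                 n_iter = 0L, label = "manual"),
            class = "op_varcomp")
}
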