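#' Back-solve SNP effects from genomic breeding values
#'
#' ssGWAS-style SNP effect recovery: with G = W W' / c (W the 2p-centered
#' code matrix, c = 2 sum p(1-p)), the SNP-BLUP effects implied by the
#' per-site GEBVs g-hat are u-hat = W' G^-1 g-hat / c. A cross-site mean
#' absolute effect is computed per SNP for ranking. When all analysed
#' individuals are genotyped, this is the single-step back-solution with an
#' empty ungenotyped set.
#'
#' @param genotypes imputed [genotype_matrix()] the G matrix was built from
#'   (same centering and denominator)
#' @param G the [relmat()] of kind "G" used in the GBLUP fit (blended or
#'   not; a singular unblended G is handled by a generalized inverse)
#' @param bvs a `breeding_values` data.frame from [predict_blup()] (one
#'   trait), or a numeric matrix of GEBVs with individuals in rows and
#'   sites in columns
#' @param trait trait to extract when `bvs` holds several
#' @return a `snp_effect_table` data.frame: snp_id, one effect column per
#'   site, and `mean_abs_effect`
#' @export
backsolve_snp_effects <- function(genotypes, G, bvs, trait = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(G, "relmat"))
  if (is.na(G$scale) || is.null(G$snp_ids))
    stop("G lacks construction metadata (scale/snp_ids); build it with build_G")
  if (inherits(bvs, "data.frame")) {
    if (is.null(trait)) {
      trait <- unique(bvs$trait)
      if (length(trait) > 1L)
        stop("bvs holds several traits; pass `trait`")
    }
    b <- bvs[bvs$trait == trait & bvs$id %in% G$ids, , drop = FALSE]
    sites <- sort(unique(b$site))
    gmat <- sapply(sites, function(s) {
      bs <- b[b$site == s, ]
      bs$bv[match(G$ids, bs$id)]
    })
    gmat <- matrix(gmat, nrow = length(G$ids),
                   dimnames = list(G$ids, sites))
  } else {
    gmat <- as.matrix(bvs)
    if (nrow(gmat) != length(G$ids))
      stop("GEBV matrix rows must match the G matrix individuals")
  }
  sel <- match(G$snp_ids, genotypes$snp_ids)
  if (anyNA(sel)) stop("G was built from SNPs absent in `genotypes`")
  if (!identical(genotypes$ids, G$ids))
    stop("genotype and G individuals differ")
  p <- genotypes$p[sel]
  W <- sweep(genotypes$codes[, sel, drop = FALSE], 2, 2 * p)
  sol <- tryCatch(solve(G$values, gmat),
                  error = function(e) MASS::ginv(G$values) %*% gmat)
  eff <- crossprod(W, sol) / G$scale
  out <- data.frame(snp_id = G$snp_ids, eff, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[-1] <- colnames(gmat)
  out$mean_abs_effect <- rowMeans(abs(eff))
  class(out) <- c("snp_effect_table", "data.frame")
  out
}

#' Rank SNPs for incremental subset construction
#'
#' Three strategies: `gwas_effect` orders by cross-site mean absolute
#' back-solved effect, largest first; `maf` orders by minor allele
#' frequency, rarest first; `random` is a seeded shuffle. Ties are broken
#' by ascending SNP identifier, making every ranking deterministic.
#'
#' @param x a `snp_effect_table` (for `gwas_effect`) or a
#'   [genotype_matrix()] (for `maf` and `random`)
#' @param strategy one of "gwas_effect", "maf", "random"
#' @param seed integer seed (random strategy only)
#' @return a `snp_ranking` list: `strategy`, ordered `snp_ids`, `seed`
#' @export
rank_snps <- function(x, strategy = c("gwas_effect", "maf", "random"),
                      seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "gwas_effect") {
    if (!inherits(x, "snp_effect_table"))
      stop("gwas_effect ranking needs a snp_effect_table")
    ord <- order(-x$mean_abs_effect, x$snp_id)
    ids <- x$snp_id[ord]
  } else if (strategy == "maf") {
    if (!inherits(x, "genotype_matrix"))
      stop("maf ranking needs a genotype_matrix")
    maf <- pmin(x$p, 1 - x$p)
    ord <- order(maf, x$snp_ids)
    ids <- x$snp_ids[ord]
  } else {
    ids0 <- if (inherits(x, "genotype_matrix")) x$snp_ids else as.character(x)
    ids <- with_sim_rng(seed, sample(ids0))
  }
  structure(list(strategy = strategy, snp_ids = ids,
                 seed = if (strategy == "random") seed else NA_integer_,
                 tie_break = "ascending snp_id"),
            class = "snp_ranking")
}

#' Cumulative SNP subset sizes
#'
#' Splits `n_total` SNPs into `n_steps` near-equal cumulative increments:
#' sizes round(j * n_total / n_steps) for j = 1..n_steps; the last size is
#' always `n_total`.
#'
#' @param n_total total SNP count
#' @param n_steps number of increments (>= 1, <= n_total)
#' @return strictly increasing integer vector ending at `n_total`
#' @export
make_increments <- function(n_total, n_steps) {
  n_total <- as.integer(n_total); n_steps <- as.integer(n_steps)
  if (n_steps < 1L || n_total < n_steps)
    stop("need n_steps >= 1 and n_total >= n_steps")
  sizes <- as.integer(round(seq_len(n_steps) * n_total / n_steps))
  sizes[n_steps] <- n_total
  if (any(diff(sizes) <= 0L)) stop("increment sizes are not strictly increasing")
  sizes
}

#' Union of each trait's top-k SNPs
#'
#' Builds the combined SNP set for a multi-trait G matrix: the union of the
#' top `k` SNPs of each trait's effect-based ranking.
#'
#' @param rankings named list (by trait) of `snp_ranking` objects over the
#'   same SNP universe
#' @param k top-k cutoff per trait
#' @return character vector of SNP ids (sorted)
#' @export
combine_trait_top <- function(rankings, k) {
  stopifnot(length(rankings) >= 1L)
  universe <- sort(rankings[[1]]$snp_ids)
  for (r in rankings) {
    if (!identical(sort(r$snp_ids), universe))
      stop("rankings cover different SNP universes")
  }
  if (k > length(universe)) stop("k exceeds the SNP universe size")
  sort(unique(unlist(lapply(rankings, function(r) head(r$snp_ids, k)))))
}

#' Subset a genotype matrix to selected SNPs
#' @param genotypes a [genotype_matrix()]
#' @param snp_ids SNPs to keep
#' @return the subset [genotype_matrix()]
#' @export
subset_snps <- function(genotypes, snp_ids) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  sel <- match(snp_ids, genotypes$snp_ids)
  if (anyNA(sel)) stop("unknown SNP id(s)")
  genotype_matrix(genotypes$codes[, sel, drop = FALSE],
                  ids = genotypes$ids, snp_ids = genotypes$snp_ids[sel],
                  imputed = genotypes$imputed)
}
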