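#' Construct a relationship-matrix object
#'
#' Thin container for a symmetric kinship/relationship matrix with its kind
#' (A = pedigree numerator, G = genomic, D = dominance, EPI = additive x
#' dominance) and construction metadata.
#'
#' @param values symmetric numeric matrix with id dimnames
#' @param kind one of "A", "G", "D", "EPI"
#' @param n_snps_used number of SNPs entering the construction (NA for A)
#' @param blend blending weight already applied towards the identity
#' @param scale denominator used in G/D construction (for SNP back-solving)
#' @param snp_ids SNPs used (G/D only)
#' @return a `relmat` object
#' @export
relmat <- function(values, kind = c("A", "G", "D", "EPI"), n_snps_used = NA_integer_,
                   blend = 0, scale = NA_real_, snp_ids = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  ids <- rownames(values)
  if (is.null(ids)) stop("relationship matrix needs id dimnames")
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8)
    stop("relationship matrix is not symmetric")
  values <- (values + t(values)) / 2
  structure(list(kind = kind, ids = ids, values = values,
                 n_snps_used = n_snps_used, blend = blend, scale = scale,
                 snp_ids = snp_ids),
            class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d individuals (mean diag %.3f%s%s)\n",
              x$kind, length(x$ids), mean(diag(x$values)),
              if (!is.na(x$n_snps_used)) sprintf(", %d SNPs", x$n_snps_used) else "",
              if (x$blend > 0) sprintf(", blend %.3g", x$blend) else ""))
  invisible(x)
}

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular-method construction of the average numerator relationship matrix
#' from a recorded pedigree. Founders are mutually unrelated and non-inbred;
#' an individual's diagonal is 1 + F where F is its inbreeding coefficient
#' (half the additive relationship of its parents). Ungenotyped parents
#' (e.g. OP seed donors without records) are included like any other
#' individual.
#'
#' @param pedigree a [pedigree_table()]
#' @return a [relmat()] of kind "A" in the pedigree's id order
#' @export
build_A <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree_table"))
  ord <- attr(pedigree, "order")
  id <- pedigree$id[ord]
  idx <- seq_along(id); names(idx) <- id
  d <- ifelse(is.na(pedigree$dam[ord]), 0L, idx[pedigree$dam[ord]])
  s <- ifelse(is.na(pedigree$sire[ord]), 0L, idx[pedigree$sire[ord]])
  n <- length(id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    if (length(prev)) {
      ai <- numeric(i - 1L)
      if (d[i] > 0L) ai <- ai + 0.5 * A[prev, d[i]]
      if (s[i] > 0L) ai <- ai + 0.5 * A[prev, s[i]]
      A[i, prev] <- ai
      A[prev, i] <- ai
    }
    A[i, i] <- 1 + if (d[i] > 0L && s[i] > 0L) 0.5 * A[d[i], s[i]] else 0
  }
  dimnames(A) <- list(id, id)
  A <- A[pedigree$id, pedigree$id, drop = FALSE]
  relmat(A, kind = "A")
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing entry by its SNP's column mean over non-missing
#' codes (a real in \[0, 2\]), leaving allele frequencies unchanged.
#' Monomorphic SNPs remain flagged.
#'
#' @param genotypes a [genotype_matrix()]
#' @return an imputed [genotype_matrix()]
#' @export
impute_and_freq <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  codes <- genotypes$codes
  if (anyNA(codes)) {
    mu <- 2 * genotypes$p
    na <- which(is.na(codes), arr.ind = TRUE)
    codes[na] <- mu[na[, 2]]
  }
  genotype_matrix(codes, ids = genotypes$ids, snp_ids = genotypes$snp_ids,
                  imputed = TRUE)
}

#' Genomic relationship matrix (G)
#'
#' VanRaden-type construction: G = W W' / (2 sum_k p_k (1 - p_k)), with W
#' the per-SNP 2 p_k-centered code matrix and p_k the observed
#' alternate-allele frequency. Monomorphic SNPs contribute nothing to
#' numerator or denominator and are excluded (with a message).
#'
#' @param genotypes an imputed [genotype_matrix()]
#' @return a [relmat()] of kind "G" with the scaling denominator recorded
#' @export
build_G <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!genotypes$imputed) stop("impute genotypes first (impute_and_freq)")
  keep <- !genotypes$monomorphic
  if (!any(keep)) stop("all SNPs are monomorphic; G denominator is zero")
  if (any(!keep)) message(sum(!keep), " monomorphic SNP(s) excluded from G")
  p <- genotypes$p[keep]
  W <- sweep(genotypes$codes[, keep, drop = FALSE], 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(genotypes$ids, genotypes$ids)
  relmat(G, kind = "G", n_snps_used = sum(keep), scale = denom,
         snp_ids = genotypes$snp_ids[keep])
}

#' Dominance relationship matrix (D)
#'
#' Vitezica-type dominance construction. Each SNP contributes a covariate
#' of -2p^2, 2pq, -2q^2 for codes 0, 1, 2 (q = 1 - p); then
#' D = W_d W_d' / sum_k (2 p_k q_k)^2. Fractional (mean-imputed) codes are
#' rounded to the nearest genotype class to assign the covariate.
#'
#' @param genotypes an imputed [genotype_matrix()]
#' @return a [relmat()] of kind "D"
#' @export
build_D <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!genotypes$imputed) stop("impute genotypes first (impute_and_freq)")
  keep <- !genotypes$monomorphic
  if (!any(keep)) stop("all SNPs are monomorphic; D denominator is zero")
  p <- genotypes$p[keep]
  q <- 1 - p
  codes <- round(genotypes$codes[, keep, drop = FALSE])
  n <- nrow(codes)
  Wd <- matrix(0, n, ncol(codes))
  for (g in 0:2) {
    cov_g <- switch(as.character(g),
                    "0" = -2 * p^2, "1" = 2 * p * q, "2" = -2 * q^2)
    idx <- which(codes == g, arr.ind = TRUE)
    Wd[idx] <- cov_g[idx[, 2]]
  }
  denom <- sum((2 * p * q)^2)
  D <- tcrossprod(Wd) / denom
  dimnames(D) <- list(genotypes$ids, genotypes$ids)
  relmat(D, kind = "D", n_snps_used = sum(keep), scale = denom,
         snp_ids = genotypes$snp_ids[keep])
}

#' Additive-by-dominance epistatic relationship matrix
#'
#' Hadamard (elementwise) product of the additive and dominance relationship
#' matrices.
#'
#' @param G,D [relmat()] objects over the same individuals
#' @return a [relmat()] of kind "EPI"
#' @export
build_epistatic <- function(G, D) {
  stopifnot(inherits(G, "relmat"), inherits(D, "relmat"))
  if (!identical(G$ids, D$ids)) stop("G and D cover different individuals")
  relmat(G$values * D$values, kind = "EPI",
         n_snps_used = G$n_snps_used)
}

#' Blend a relationship matrix towards the identity
#'
#' K <- (1 - w) K + w I. A genomic matrix built from fewer SNPs than
#' individuals is singular; a small blend restores invertibility before the
#' mixed-model equations take its inverse. The weight is recorded in the
#' object.
#'
#' @param K a [relmat()]
#' @param weight blending weight in \[0, 1)
#' @return the blended [relmat()]
#' @export
blend_relmat <- function(K, weight = 0.01) {
  stopifnot(inherits(K, "relmat"), weight >= 0, weight < 1)
  if (weight == 0) return(K)
  V <- (1 - weight) * K$values + weight * diag(nrow(K$values))
  dimnames(V) <- dimnames(K$values)
  relmat(V, kind = K$kind, n_snps_used = K$n_snps_used,
         blend = K$blend + weight, scale = K$scale, snp_ids = K$snp_ids)
}

#' Genomic verification of a recorded pedigree
#'
#' Uses realized genomic relationships to audit family records of
#' open-pollinated offspring. In order: (1) individuals with a G diagonal
#' below `diag_low` are removed (poor genotyping / clones artefacts);
#' (2) individuals whose mean relationship to the other members of their
#' recorded family falls below `within_family_low` are tested against every
#' other family and reassigned to the best-matching family when that mean
#' is at least `cluster_min`; (3) remaining mislabels that are mutually
#' related at `cluster_min` or more are grouped into new families;
#' (4) leftovers are reported unassigned.
#'
#' @param G genomic [relmat()] covering the genotyped offspring
#' @param pedigree_recorded recorded [pedigree_table()] (families = dams)
#' @param thresholds named numeric vector with `diag_low`,
#'   `within_family_low` and `cluster_min`
#' @return a `qc_report` list with elements `removed_low_diagonal`,
#'   `reassigned` (data.frame id/old_family/new_family), `new_families`
#'   (named list of id vectors), `unassigned`, and `final_ids`
#' @export
verify_pedigree <- function(G, pedigree_recorded,
                            thresholds = c(diag_low = 0.6,
                                           within_family_low = 0.1,
                                           cluster_min = 0.15)) {
  stopifnot(inherits(G, "relmat"), inherits(pedigree_recorded, "pedigree_table"))
  th <- thresholds
  ped <- pedigree_recorded[!is.na(pedigree_recorded$dam), , drop = FALSE]
  ped <- ped[ped$id %in% G$ids, , drop = FALSE]
  fam <- setNames(ped$dam, ped$id)
  V <- G$values
  removed <- G$ids[diag(V)[match(G$ids, rownames(V))] < th[["diag_low"]]]
  keep <- setdiff(names(fam), removed)
  fam <- fam[keep]
  fam_ids <- split(names(fam), fam)

  mean_rel <- function(i, members) {
    members <- setdiff(members, i)
    if (!length(members)) return(NA_real_)
    mean(V[i, members])
  }
  suspects <- character(0)
  for (i in names(fam)) {
    wr <- mean_rel(i, fam_ids[[fam[[i]]]])
    if (!is.na(wr) && wr < th[["within_family_low"]]) suspects <- c(suspects, i)
  }
  reassigned <- data.frame(id = character(0), old_family = character(0),
                           new_family = character(0), stringsAsFactors = FALSE)
  leftover <- character(0)
  for (i in suspects) {
    other <- fam_ids[names(fam_ids) != fam[[i]]]
    if (length(other)) {
      means <- vapply(other, function(m) mean_rel(i, setdiff(m, suspects)),
                      numeric(1))
      means[is.na(means)] <- -Inf
      best <- which.max(means)
      if (means[best] >= th[["cluster_min"]]) {
        reassigned <- rbind(reassigned,
                            data.frame(id = i, old_family = fam[[i]],
                                       new_family = names(other)[best],
                                       stringsAsFactors = FALSE))
        next
      }
    }
    leftover <- c(leftover, i)
  }
  # cluster mutually related leftovers into new families
  new_families <- list()
  unassigned <- character(0)
  if (length(leftover)) {
    adj <- V[leftover, leftover, drop = FALSE] >= th[["cluster_min"]]
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      mem <- leftover[comp$membership == k]
      if (length(mem) >= 2L) {
        new_families[[paste0("NEWFAM", length(new_families) + 1L)]] <- mem
      } else {
        unassigned <- c(unassigned, mem)
      }
    }
  }
  structure(list(removed_low_diagonal = removed,
                 reassigned = reassigned,
                 new_families = new_families,
                 unassigned = unassigned,
                 final_ids = setdiff(ped$id, removed),
                 thresholds = th),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("pedigree QC: %d removed (low diagonal), %d reassigned, ",
                     "%d new famil%s, %d unassigned; %d individuals retained\n"),
              length(x$removed_low_diagonal), nrow(x$reassigned),
              length(x$new_families),
              if (length(x$new_families) == 1) "y" else "ies",
              length(x$unassigned), length(x$final_ids)))
  invisible(x)
}

#' Threshold kinship network
#'
#' Links every unordered pair whose relationship exceeds `threshold` and
#' reports the connected components of the resulting graph (isolated
#' individuals form singleton components).
#'
#' @param K a [relmat()]
#' @param threshold minimum relationship for an edge (exclusive)
#' @return a `kinship_network` list with `threshold`, `edges` (data.frame
#'   id1/id2/value) and `components` (list of id vectors)
#' @export
network_edges <- function(K, threshold) {
  stopifnot(inherits(K, "relmat"), threshold >= 0)
  V <- K$values
  ut <- which(upper.tri(V) & V > threshold, arr.ind = TRUE)
  edges <- data.frame(id1 = K$ids[ut[, 1]], id2 = K$ids[ut[, 2]],
                      value = V[ut], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = K$ids))
  comp <- igraph::components(g)
  components <- split(K$ids, comp$membership[K$ids])
  names(components) <- NULL
  structure(list(threshold = threshold, edges = edges, components = components),
            class = "kinship_network")
}

#' @export
print.kinship_network <- function(x, ...) {
  cat(sprintf("kinship network (threshold %g): %d edges, %d components\n",
              x$threshold, nrow(x$edges), length(x$components)))
  invisible(x)
}
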