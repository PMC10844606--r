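#' @importFrom stats rnorm rbinom runif var sd cor setNames
#' @importFrom utils head combn
NULL

# Single internal sentinel for unknown parents.
.UNKNOWN <- NA_character_

#' Detect the field delimiter of a delimited text file
#'
#' Looks at the first line and prefers tab over comma; used by all readers so
#' that CSV and TSV dialects are both accepted.
#' @param path file path
#' @return a single character, `"\t"` or `","`
#' @keywords internal
sniff_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stop("file is empty: ", path)
  if (grepl("\t", line)) "\t" else ","
}

#' Construct a validated pedigree table
#'
#' A pedigree table holds one row per individual with its recorded dam and
#' sire; unknown parents are `NA`. Open-pollinated offspring typically have a
#' known dam and an unknown sire. Validation enforces unique ids, parents
#' present in the table (or unknown), and acyclicity; a topological ordering
#' (parents before offspring) is stored as attribute `"order"`.
#'
#' @param id,dam,sire character vectors of equal length; `NA` marks an
#'   unknown parent
#' @return a `pedigree_table` (a `data.frame` with columns id, dam, sire)
#' @export
pedigree_table <- function(id, dam, sire) {
  id <- as.character(id); dam <- as.character(dam); sire <- as.character(sire)
  if (length(dam) != length(id) || length(sire) != length(id))
    stop("id, dam and sire must have equal length")
  if (anyNA(id)) stop("individual ids must not be missing")
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  for (p in list(dam, sire)) {
    bad <- !is.na(p) & !(p %in% id)
    if (any(bad)) {
      stop("parent id(s) not present in pedigree: ",
           paste(unique(p[bad]), collapse = ", "))
    }
  }
  ord <- pedigree_toposort(id, dam, sire)  # errors on cycles
  out <- data.frame(id = id, dam = dam, sire = sire, stringsAsFactors = FALSE)
  attr(out, "order") <- ord
  class(out) <- c("pedigree_table", "data.frame")
  out
}

# Kahn topological sort; returns an integer permutation such that parents
# precede offspring. Errors when a cycle exists (an individual its own
# ancestor).
pedigree_toposort <- function(id, dam, sire) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  pd <- ifelse(is.na(dam), 0L, idx[dam])
  ps <- ifelse(is.na(sire), 0L, idx[sire])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(c(pd[i], ps[i]))) {
      if (p > 0L && p != i) {
        children[[p]] <- c(children[[p]], i)
        indeg[i] <- indeg[i] + 1L
      } else if (p == i) {
        stop("pedigree cycle: individual '", id[i], "' is its own parent")
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n)
    stop("pedigree cycle detected involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' Read a pedigree file
#'
#' Expects a delimited file (comma or tab, auto-detected) with a header row
#' naming three columns: individual id, dam, sire. Any of the tokens in
#' `unknown_token` (plus empty strings) are normalized to `NA` (unknown
#' parent).
#'
#' @param path path to the pedigree file
#' @param unknown_token character vector of tokens coding an unknown parent
#' @return a [pedigree_table()]
#' @export
read_pedigree <- function(path, unknown_token = c("NA", "0", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sniff_delim(path), header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(dt) < 3L) stop("pedigree file needs at least 3 columns (id, dam, sire)")
  dt <- as.data.frame(dt)[, 1:3]
  norm <- function(x) { x[x %in% unknown_token | is.na(x)] <- .UNKNOWN; x }
  pedigree_table(dt[[1]], norm(dt[[2]]), norm(dt[[3]]))
}

#' Write a pedigree table
#' @param ped a [pedigree_table()]
#' @param path output path; `.tsv` extension selects tab delimiter
#' @param unknown_token token used to write unknown parents
#' @export
write_pedigree <- function(ped, path, unknown_token = "NA") {
  stopifnot(inherits(ped, "pedigree_table"))
  out <- as.data.frame(ped)
  out$dam[is.na(out$dam)] <- unknown_token
  out$sire[is.na(out$sire)] <- unknown_token
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Founders of a pedigree
#' @param ped a [pedigree_table()]
#' @return character vector of ids with both parents unknown
#' @export
pedigree_founders <- function(ped) {
  ped$id[is.na(ped$dam) & is.na(ped$sire)]
}

#' Construct a genotype matrix object
#'
#' Wraps an individuals-by-SNP matrix of allele counts (0/1/2, `NA` for
#' missing; fractional values are allowed after mean imputation) together
#' with per-SNP observed alternate-allele frequencies computed over
#' non-missing entries only.
#'
#' @param codes numeric matrix, individuals in rows, SNPs in columns
#' @param ids individual ids (defaults to rownames)
#' @param snp_ids SNP ids (defaults to colnames)
#' @param imputed logical flag: no missing entries remain
#' @return a `genotype_matrix` with elements `ids`, `snp_ids`, `codes`, `p`
#'   (alternate-allele frequency per SNP), `monomorphic` (logical per SNP)
#'   and `imputed`
#' @export
genotype_matrix <- function(codes, ids = rownames(codes),
                            snp_ids = colnames(codes), imputed = FALSE) {
  codes <- as.matrix(codes)
  if (is.null(ids) || is.null(snp_ids))
    stop("ids and snp_ids are required (or set dimnames on `codes`)")
  ids <- as.character(ids); snp_ids <- as.character(snp_ids)
  if (nrow(codes) != length(ids) || ncol(codes) != length(snp_ids))
    stop("dimensions of `codes` do not match id lists")
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  nm <- colSums(!is.na(codes))
  if (any(nm == 0L))
    stop("SNP(s) with all entries missing: ",
         paste(snp_ids[nm == 0L], collapse = ", "))
  rng <- range(codes, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("genotype codes must lie in [0, 2]")
  p <- colMeans(codes, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  dimnames(codes) <- list(ids, snp_ids)
  structure(list(ids = ids, snp_ids = snp_ids, codes = codes, p = unname(p),
                 monomorphic = unname(mono),
                 imputed = isTRUE(imputed) || !anyNA(codes)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d monomorphic, %s)\n",
              length(x$ids), length(x$snp_ids), sum(x$monomorphic),
              if (x$imputed) "imputed/complete" else
                sprintf("%.1f%% missing", 100 * mean(is.na(x$codes)))))
  invisible(x)
}

#' Read a genotype table
#'
#' Rectangular delimited table: first column individual ids, remaining
#' columns SNP allele counts in \{0, 1, 2\}. Missing entries are coded by any
#' of `missing_token`. SNPs whose missing fraction exceeds `max_missing` are
#' dropped with a message (mean imputation degrades beyond that point).
#'
#' @param path file path
#' @param missing_token tokens coding a missing genotype
#' @param max_missing per-SNP missingness cap in \[0, 1\]
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, missing_token = c("NA", ""), max_missing = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sniff_delim(path), header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(dt) < 2L) stop("genotype file needs an id column plus >= 1 SNP column")
  ids <- as.character(dt[[1]])
  snp_ids <- colnames(dt)[-1]
  raw <- as.matrix(dt[, -1])
  raw[raw %in% missing_token] <- NA
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- !is.na(raw) & (is.na(num) | !(num %in% c(0, 1, 2)))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code '%s' at individual '%s', SNP '%s' (must be 0/1/2 or missing)",
                 raw[bad][1], ids[i[1]], snp_ids[i[2]]))
  }
  miss <- colMeans(is.na(num))
  if (any(miss > max_missing)) {
    drop <- miss > max_missing
    message(sum(drop), " SNP(s) dropped for missingness > ", max_missing)
    num <- num[, !drop, drop = FALSE]
    snp_ids <- snp_ids[!drop]
    if (ncol(num) == 0L) stop("no SNPs left after the missingness cap")
  }
  genotype_matrix(num, ids = ids, snp_ids = snp_ids)
}

#' Write a genotype matrix
#' @param geno a [genotype_matrix()]
#' @param path output path (`.tsv` for tab-delimited)
#' @param missing_token token written for missing entries
#' @export
write_genotypes <- function(geno, path, missing_token = "NA") {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(id = geno$ids, geno$codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(df, path, sep = sep, quote = FALSE, na = missing_token)
  invisible(path)
}

#' Construct a validated long-format phenotype table
#'
#' One row per (individual, site, trait) observation with a replication
#' label. Validation enforces unique (individual, site, trait) keys, each
#' individual confined to a single site (trees do not move), and traits
#' drawn from a declared list.
#'
#' @param df data.frame with columns `id`, `site`, `rep`, `trait`, `value`
#' @param trait_list declared traits; rows with other traits are an error
#' @return a `phenotype_table` (a `data.frame`)
#' @export
phenotype_table <- function(df, trait_list = unique(df$trait)) {
  need <- c("id", "site", "rep", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$id <- as.character(df$id); df$site <- as.character(df$site)
  df$rep <- as.character(df$rep); df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  bad <- !(df$trait %in% trait_list)
  if (any(bad))
    stop("trait(s) outside the declared trait list at row(s) ",
         paste(head(which(bad), 5L), collapse = ", "), ": ",
         paste(unique(df$trait[bad]), collapse = ", "))
  key <- paste(df$id, df$site, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    stop("duplicate (individual, site, trait) record(s), e.g. (",
         d$id[1], ", ", d$site[1], ", ", d$trait[1], ")")
  }
  ns <- tapply(df$site, df$id, function(s) length(unique(s)))
  if (any(ns > 1L))
    stop("individual(s) recorded in more than one site: ",
         paste(names(ns)[ns > 1L][1:min(5, sum(ns > 1))], collapse = ", "))
  attr(df, "trait_list") <- trait_list
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a long-format phenotype file
#'
#' Delimited file with columns id, site, rep, trait, value (header required;
#' comma or tab auto-detected).
#'
#' @param path file path
#' @param trait_list declared traits (e.g. `c("HT", "DBH", "WD")`)
#' @return a [phenotype_table()]
#' @export
read_phenotypes <- function(path, trait_list) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path, sep = sniff_delim(path),
                                        header = TRUE))
  if (ncol(dt) < 5L) stop("phenotype file needs 5 columns (id, site, rep, trait, value)")
  names(dt)[1:5] <- c("id", "site", "rep", "trait", "value")
  phenotype_table(dt[, 1:5], trait_list = trait_list)
}

#' Write a phenotype table
#' @param phe a [phenotype_table()]
#' @param path output path (`.tsv` for tab-delimited)
#' @export
write_phenotypes <- function(phe, path) {
  stopifnot(inherits(phe, "phenotype_table"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(as.data.frame(phe), path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read a relationship matrix from TSV
#'
#' Format written by [write_relmat()]: a square table with id header row and
#' id first column.
#' @param path file path
#' @param kind matrix kind label ("A", "G", "D" or "EPI")
#' @return a [relmat()]
#' @export
read_relmat <- function(path, kind = "G") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1])
  dimnames(m) <- list(ids, colnames(dt)[-1])
  if (!identical(ids, colnames(m)))
    stop("relationship matrix row and column ids differ")
  relmat(m, kind = kind)
}

#' Write a relationship matrix to TSV
#' @param K a [relmat()]
#' @param path output path
#' @export
write_relmat <- function(K, path) {
  stopifnot(inherits(K, "relmat"))
  df <- data.frame(id = K$ids, K$values, check.names = FALSE)
  colnames(df) <- c("id", K$ids)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
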