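#' Specify an individual-tree mixed model
#'
#' Defines the multi-site (single-trait) or multi-trait multi-site
#' individual-tree model: a fixed intercept per response key (site, or
#' trait-site combination), one or more genetic random terms (additive, and
#' optionally dominance and additive-by-dominance epistatic), each with an
#' unstructured covariance across response keys and a relationship matrix
#' across individuals, and a residual that is unstructured across traits
#' within a site and zero across sites (trees are measured at one site
#' only).
#'
#' @param traits character vector of traits to model jointly; length 1 gives
#'   the single-trait multi-site model, length > 1 the multi-trait
#'   multi-site model
#' @param kinship named list of [relmat()] objects over identical ids; names
#'   from `additive` (required), `dominance`, `epistatic`
#' @param label model label (e.g. "ABLUP", "GBLUP-A", "GBLUP-ADE",
#'   "GBLUP-ALL", "GBLUP-GWAS")
#' @return a `model_spec` object
#' @export
model_spec <- function(traits, kinship, label = "GBLUP-A") {
  if (!length(traits)) stop("at least one trait is required")
  if (!is.list(kinship) || is.null(names(kinship)))
    stop("kinship must be a named list of relmat objects")
  ok <- c("additive", "dominance", "epistatic")
  if (!all(names(kinship) %in% ok))
    stop("kinship names must be among: ", paste(ok, collapse = ", "))
  if (!"additive" %in% names(kinship)) stop("an additive term is required")
  kinship <- kinship[intersect(ok, names(kinship))]
  for (K in kinship) stopifnot(inherits(K, "relmat"))
  ids <- kinship[[1]]$ids
  for (K in kinship) {
    if (!identical(K$ids, ids))
      stop("all relationship matrices must cover the same individuals")
  }
  structure(list(traits = as.character(traits), kinship = kinship,
                 label = label),
            class = "model_spec")
}

# Shared preparation: response keys, observation table, complete-case
# filtering and bookkeeping used by assemble/fit/predict.
prepare_model_data <- function(spec, phenotypes) {
  stopifnot(inherits(spec, "model_spec"), inherits(phenotypes, "phenotype_table"))
  traits <- spec$traits
  phe <- phenotypes[phenotypes$trait %in% traits, , drop = FALSE]
  if (!nrow(phe)) stop("no phenotype records for the requested trait(s)")
  ids <- spec$kinship[[1]]$ids
  missing_ids <- setdiff(unique(phe$id), ids)
  if (length(missing_ids))
    stop("phenotyped individual(s) absent from the relationship matrix: ",
         paste(head(missing_ids, 5), collapse = ", "))
  sites <- sort(unique(phe$site))
  nt <- length(traits)
  keys <- data.frame(site = rep(sites, each = nt),
                     trait = rep(traits, times = length(sites)),
                     stringsAsFactors = FALSE)
  keys$label <- paste0(keys$trait, "@", keys$site)
  q <- nrow(keys)
  # complete-case within (individual, site): multi-trait residual blocks
  # need all traits observed
  if (nt > 1L) {
    cnt <- table(phe$id)
    incomplete <- names(cnt)[cnt < nt]
    if (length(incomplete)) {
      message(length(incomplete),
              " individual(s) dropped with incomplete trait records")
      phe <- phe[!(phe$id %in% incomplete), , drop = FALSE]
    }
  }
  key_of <- match(paste0(phe$trait, "@", phe$site), keys$label)
  i_of <- match(phe$id, ids)
  ord <- order(i_of, key_of)
  obs <- data.frame(i = i_of[ord], k = key_of[ord], y = phe$value[ord])
  site_of_key <- keys$site
  list(ids = ids, n = length(ids), keys = keys, q = q, traits = traits,
       sites = sites, nt = nt, obs = obs, N = nrow(obs),
       rows_by_ind = split(seq_len(nrow(obs)), obs$i),
       site_of_obs = keys$site[obs$k])
}

# sparse joint design [X | Z_term1 | Z_term2 | ...]; fixed part is one
# intercept per key, random part one column per (key, individual) per term
build_design <- function(pd, nterms) {
  N <- pd$N; q <- pd$q; n <- pd$n
  rows <- seq_len(N)
  jx <- pd$obs$k
  jz <- q + (pd$obs$k - 1L) * n + pd$obs$i
  ii <- rep(rows, 1L + nterms)
  jj <- c(jx, unlist(lapply(seq_len(nterms), function(t) jz + (t - 1L) * q * n)))
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(N, q + nterms * q * n))
}

# sparse block-diagonal residual inverse; one block per individual over its
# observed keys
build_rinv <- function(pd, resid) {
  triplets_i <- integer(0); triplets_j <- integer(0); triplets_x <- numeric(0)
  Rinv_site <- lapply(resid, function(R) chol2inv(chol(R)))
  for (rows in pd$rows_by_ind) {
    s <- pd$site_of_obs[rows[1L]]
    tr_idx <- match(pd$keys$trait[pd$obs$k[rows]], pd$traits)
    Ri <- Rinv_site[[s]][tr_idx, tr_idx, drop = FALSE]
    nb <- length(rows)
    triplets_i <- c(triplets_i, rep(rows, times = nb))
    triplets_j <- c(triplets_j, rep(rows, each = nb))
    triplets_x <- c(triplets_x, as.vector(Ri))
  }
  Matrix::sparseMatrix(i = triplets_i, j = triplets_j, x = triplets_x,
                       dims = c(pd$N, pd$N))
}

# eigenvalue clipping keeps unstructured covariance matrices positive
# definite as EM drifts near the boundary
psd_clip <- function(M, rel = 1e-8) {
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  lo <- rel * max(abs(eg$values), 1e-300)
  if (all(eg$values >= lo)) return(M)
  vals <- pmax(eg$values, lo)
  M2 <- eg$vectors %*% (vals * t(eg$vectors))
  dimnames(M2) <- dimnames(M)
  (M2 + t(M2)) / 2
}

default_init <- function(pd, nterms) {
  vk <- vapply(seq_len(pd$q), function(k) {
    v <- stats::var(pd$obs$y[pd$obs$k == k])
    if (!is.finite(v) || v <= 0) 1 else v
  }, numeric(1))
  terms <- vector("list", nterms)
  for (t in seq_len(nterms)) {
    S <- diag(0.5 * vk / nterms, pd$q)
    # small positive covariance between sites for the same trait breaks the
    # symmetry needed to recover correlated site-specific genetic effects
    for (k in seq_len(pd$q)) for (l in seq_len(pd$q)) {
      if (k != l && pd$keys$trait[k] == pd$keys$trait[l])
        S[k, l] <- 0.1 * sqrt(vk[k] * vk[l]) / nterms
    }
    dimnames(S) <- list(pd$keys$label, pd$keys$label)
    terms[[t]] <- S
  }
  resid <- lapply(pd$sites, function(s) {
    ks <- which(pd$keys$site == s)
    R <- diag(0.5 * vk[ks], length(ks))
    dimnames(R) <- list(pd$keys$trait[ks], pd$keys$trait[ks])
    R
  })
  names(resid) <- pd$sites
  list(terms = terms, resid = resid)
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the symmetric coefficient matrix and right-hand side of the MME
#' for a [model_spec()] at given variance components: the random-effect
#' blocks add (inverse covariance across keys) Kronecker (inverse
#' relationship matrix) to the data part.
#'
#' @param spec a [model_spec()]
#' @param phenotypes adjusted [phenotype_table()]
#' @param varcomp an `op_varcomp` from [fit_reml()] (or a compatible list
#'   with elements `terms` and `resid`)
#' @return list with `C` (dense coefficient matrix), `rhs`, and `layout`
#'   describing the (effect, key, individual) to index map
#' @export
assemble_mme <- function(spec, phenotypes, varcomp) {
  pd <- prepare_model_data(spec, phenotypes)
  nterms <- length(spec$kinship)
  Tm <- build_design(pd, nterms)
  Rinv <- build_rinv(pd, varcomp$resid)
  C <- as.matrix(Matrix::crossprod(Tm, Rinv %*% Tm))
  rhs <- as.numeric(Matrix::crossprod(Tm, Rinv %*% pd$obs$y))
  qn <- pd$q * pd$n
  Kinvs <- lapply(spec$kinship, function(K) chol2inv(chol(K$values)))
  for (t in seq_len(nterms)) {
    Sinv <- chol2inv(chol(psd_clip(varcomp$terms[[t]])))
    blk <- pd$q + (t - 1L) * qn + seq_len(qn)
    C[blk, blk] <- C[blk, blk] + kronecker(Sinv, Kinvs[[t]])
  }
  layout <- list(p = pd$q, n = pd$n, q = pd$q, ids = pd$ids, keys = pd$keys,
                 terms = names(spec$kinship),
                 random_offset = setNames(pd$q + (seq_len(nterms) - 1L) * qn,
                                          names(spec$kinship)))
  list(C = C, rhs = rhs, layout = layout)
}

#' Fit variance components by EM-REML with an average-information round
#'
#' Iterates expectation-maximization REML updates of the unstructured
#' genetic covariance matrices and the within-site residual blocks until
#' the relative change in restricted log-likelihood falls below `tol`, then
#' performs one average-information (AI) round whose inverse supplies
#' standard errors for every variance parameter. The restricted
#' log-likelihood is non-decreasing along EM iterations (up to the
#' positive-definiteness clipping applied to drifting covariance matrices).
#'
#' A single-key model with one genetic term (single trait, single site) is
#' fitted through an exact spectral shortcut: the relationship matrix of the
#' recorded individuals is eigendecomposed once and every EM iteration costs
#' O(n). The fixed point is identical to the general solver's.
#'
#' @param spec a [model_spec()]
#' @param phenotypes adjusted [phenotype_table()]
#' @param init optional starting values (list with `terms`, `resid`)
#' @param tol relative restricted log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations; when reached, `converged` is FALSE
#'   and results are still returned
#' @param verbose print the likelihood every 25 iterations
#' @return an `op_varcomp` object: genetic covariance matrix per term
#'   (`terms`), per-site residual matrices (`resid`), parameter standard
#'   errors (`se`), AI covariance of the estimates (`vcov_params`),
#'   log-likelihood trace, convergence flag and iteration count
#' @export
fit_reml <- function(spec, phenotypes, init = NULL, tol = 1e-8,
                     max_iter = 2000L, verbose = FALSE) {
  pd <- prepare_model_data(spec, phenotypes)
  nterms <- length(spec$kinship)
  if (pd$q == 1L && nterms == 1L) {
    return(fit_reml_spectral(spec, pd, init, tol, max_iter))
  }
  Tm <- build_design(pd, nterms)
  y <- pd$obs$y
  qn <- pd$q * pd$n
  Kinvs <- vector("list", nterms); logdetK <- numeric(nterms)
  for (t in seq_len(nterms)) {
    ch <- chol(spec$kinship[[t]]$values)
    Kinvs[[t]] <- chol2inv(ch)
    logdetK[t] <- 2 * sum(log(diag(ch)))
  }
  vc <- if (is.null(init)) default_init(pd, nterms) else init
  n_site <- table(factor(vapply(pd$rows_by_ind,
                                function(r) pd$site_of_obs[r[1L]],
                                character(1)), levels = pd$sites))

  ll_trace <- numeric(0)
  converged <- FALSE
  chC <- NULL; Rinv <- NULL
  blk_of <- function(t, k) pd$q + (t - 1L) * qn + (k - 1L) * pd$n + seq_len(pd$n)
  for (iter in seq_len(max_iter)) {
    Rinv <- build_rinv(pd, vc$resid)
    C <- as.matrix(Matrix::crossprod(Tm, Rinv %*% Tm))
    rhs <- as.numeric(Matrix::crossprod(Tm, Rinv %*% y))
    Sinvs <- vector("list", nterms); logdetS <- numeric(nterms)
    for (t in seq_len(nterms)) {
      St <- psd_clip(vc$terms[[t]])
      ch <- chol(St)
      Sinvs[[t]] <- chol2inv(ch)
      logdetS[t] <- 2 * sum(log(diag(ch)))
      blk <- pd$q + (t - 1L) * qn + seq_len(qn)
      C[blk, blk] <- C[blk, blk] + kronecker(Sinvs[[t]], Kinvs[[t]])
    }
    chC <- chol(C)
    theta <- backsolve(chC, forwardsolve(t(chC), rhs))
    Ci <- chol2inv(chC)
    yRy <- sum(y * as.numeric(Rinv %*% y))
    yPy <- yRy - sum(theta * rhs)
    logdetR <- sum(vapply(pd$sites, function(s) {
      n_site[[s]] * determinant(vc$resid[[s]], logarithm = TRUE)$modulus
    }, numeric(1)))
    ll <- -0.5 * (logdetR +
                    sum(pd$n * logdetS + pd$q * logdetK) +
                    2 * sum(log(diag(chC))) + yPy)
    ll_trace <- c(ll_trace, ll)
    if (verbose && iter %% 25L == 0L)
      message(sprintf("iter %d: logLik %.6f", iter, ll))

    # EM update of each term's key-by-key covariance
    for (t in seq_len(nterms)) {
      S_new <- matrix(0, pd$q, pd$q)
      for (k in seq_len(pd$q)) for (l in k:pd$q) {
        bk <- blk_of(t, k); bl <- blk_of(t, l)
        uk <- theta[bk]; ul <- theta[bl]
        num <- drop(crossprod(uk, Kinvs[[t]] %*% ul)) +
          sum(Kinvs[[t]] * t(Ci[bk, bl]))
        S_new[k, l] <- S_new[l, k] <- num / pd$n
      }
      dimnames(S_new) <- dimnames(vc$terms[[t]])
      vc$terms[[t]] <- psd_clip(S_new)
    }
    # EM update of within-site residual blocks
    ehat <- y - as.numeric(Tm %*% theta)
    Q <- as.matrix(Tm %*% Ci)
    if (pd$nt == 1L) {
      dCT <- Matrix::rowSums(Q * Tm)
      for (s in pd$sites) {
        at <- which(pd$site_of_obs == s)
        vc$resid[[s]][1, 1] <- (sum(ehat[at]^2) + sum(dCT[at])) / length(at)
      }
    } else {
      acc <- lapply(pd$sites, function(s) matrix(0, pd$nt, pd$nt))
      names(acc) <- pd$sites
      for (rows in pd$rows_by_ind) {
        s <- pd$site_of_obs[rows[1L]]
        tr_idx <- match(pd$keys$trait[pd$obs$k[rows]], pd$traits)
        Ei <- tcrossprod(ehat[rows]) +
          as.matrix(Q[rows, , drop = FALSE] %*% Matrix::t(Tm[rows, , drop = FALSE]))
        acc[[s]][tr_idx, tr_idx] <- acc[[s]][tr_idx, tr_idx] + Ei
      }
      for (s in pd$sites) {
        Rs <- psd_clip(acc[[s]] / n_site[[s]])
        dimnames(Rs) <- dimnames(vc$resid[[s]])
        vc$resid[[s]] <- Rs
      }
    }
    if (iter > 1L) {
      dll <- ll_trace[iter] - ll_trace[iter - 1L]
      if (abs(dll) / (abs(ll_trace[iter]) + 1) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  ai <- ai_round(spec, pd, vc, Tm)
  new_varcomp(vc, pd, spec, ll_trace, converged, ai)
}

# parameter bookkeeping: lower-triangular elements of each term covariance,
# then of each within-site residual block
param_index <- function(pd, nterms) {
  nm <- character(0); what <- list()
  for (t in seq_len(nterms)) {
    for (k in seq_len(pd$q)) for (l in seq_len(k)) {
      nm <- c(nm, sprintf("Sg%d.%s:%s", t, pd$keys$label[k], pd$keys$label[l]))
      what[[length(what) + 1L]] <- list(type = "term", t = t, k = k, l = l)
    }
  }
  for (s in pd$sites) {
    for (i in seq_len(pd$nt)) for (j in seq_len(i)) {
      nm <- c(nm, sprintf("R.%s.%s:%s", s, pd$traits[i], pd$traits[j]))
      what[[length(what) + 1L]] <- list(type = "resid", s = s, i = i, j = j)
    }
  }
  list(names = nm, what = what)
}

param_vector <- function(vc, pd, pidx) {
  vapply(pidx$what, function(w) {
    if (w$type == "term") vc$terms[[w$t]][w$k, w$l]
    else vc$resid[[w$s]][w$i, w$j]
  }, numeric(1))
}

# one average-information round at the converged estimates; returns the AI
# matrix and the covariance (its inverse) over all variance parameters
ai_round <- function(spec, pd, vc, Tm) {
  nterms <- length(spec$kinship)
  qn <- pd$q * pd$n
  y <- pd$obs$y
  Rinv <- build_rinv(pd, vc$resid)
  C <- as.matrix(Matrix::crossprod(Tm, Rinv %*% Tm))
  rhs <- as.numeric(Matrix::crossprod(Tm, Rinv %*% y))
  Ks <- lapply(spec$kinship, function(K) K$values)
  for (t in seq_len(nterms)) {
    Sinv <- chol2inv(chol(psd_clip(vc$terms[[t]])))
    blk <- pd$q + (t - 1L) * qn + seq_len(qn)
    C[blk, blk] <- C[blk, blk] + kronecker(Sinv, chol2inv(chol(Ks[[t]])))
  }
  chC <- chol(C)
  theta <- backsolve(chC, forwardsolve(t(chC), rhs))
  Py <- as.numeric(Rinv %*% (y - as.numeric(Tm %*% theta)))
  Papply <- function(f) {
    w <- as.numeric(Matrix::crossprod(Tm, Rinv %*% f))
    as.numeric(Rinv %*% f) -
      as.numeric(Rinv %*% (Tm %*% backsolve(chC, forwardsolve(t(chC), w))))
  }
  pidx <- param_index(pd, nterms)
  np <- length(pidx$names)
  # working vectors f_j = dV/dtheta_j %*% Py
  obs_col <- function(k) which(pd$obs$k == k)  # obs rows at key k
  fs <- matrix(0, pd$N, np)
  for (j in seq_len(np)) {
    w <- pidx$what[[j]]
    f <- numeric(pd$N)
    if (w$type == "term") {
      K <- Ks[[w$t]]
      # u-space working vector per key, mapped through the incidence
      wk <- numeric(pd$n); wl <- numeric(pd$n)
      rk <- obs_col(w$k); rl <- obs_col(w$l)
      wk[pd$obs$i[rk]] <- Py[rk]
      wl[pd$obs$i[rl]] <- Py[rl]
      vk <- K %*% wl
      f[rk] <- f[rk] + vk[pd$obs$i[rk]]
      if (w$k != w$l) {
        vl <- K %*% wk
        f[rl] <- f[rl] + vl[pd$obs$i[rl]]
      }
    } else {
      ks_i <- which(pd$keys$site == w$s & pd$keys$trait == pd$traits[w$i])
      ks_j <- which(pd$keys$site == w$s & pd$keys$trait == pd$traits[w$j])
      ri <- obs_col(ks_i); rj <- obs_col(ks_j)
      # residual blocks pair records of the same individual
      mi <- pd$obs$i[ri]; mj <- pd$obs$i[rj]
      f[ri] <- f[ri] + Py[rj][match(mi, mj)]
      if (w$i != w$j) f[rj] <- f[rj] + Py[ri][match(mj, mi)]
    }
    f[is.na(f)] <- 0
    fs[, j] <- f
  }
  Pf <- apply(fs, 2, Papply)
  AI <- 0.5 * crossprod(fs, Pf)
  AI <- (AI + t(AI)) / 2
  vcov <- tryCatch(solve(AI), error = function(e) MASS::ginv(AI))
  dimnames(AI) <- dimnames(vcov) <- list(pidx$names, pidx$names)
  list(AI = AI, vcov = vcov, pidx = pidx)
}

new_varcomp <- function(vc, pd, spec, ll_trace, converged, ai) {
  pvec <- param_vector(vc, pd, ai$pidx)
  names(pvec) <- ai$pidx$names
  structure(list(terms = setNames(vc$terms, names(spec$kinship)),
                 resid = vc$resid,
                 keys = pd$keys, traits = pd$traits, sites = pd$sites,
                 params = pvec,
                 se = sqrt(pmax(diag(ai$vcov), 0)),
                 vcov_params = ai$vcov,
                 loglik = ll_trace,
                 converged = converged,
                 n_iter = length(ll_trace),
                 label = spec$label),
            class = "op_varcomp")
}

#' @export
print.op_varcomp <- function(x, ...) {
  cat(sprintf("%s variance components (%d keys, %s after %d EM iterations)\n",
              x$label, nrow(x$keys),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  for (t in names(x$terms)) {
    cat(" ", t, "variances:", paste(sprintf("%.4g", diag(x$terms[[t]])),
                                    collapse = ", "), "\n")
  }
  cat("  residual variances:",
      paste(sprintf("%.4g", unlist(lapply(x$resid, diag))), collapse = ", "),
      "\n")
  invisible(x)
}

# spectral fast path: single key, single genetic term
fit_reml_spectral <- function(spec, pd, init, tol, max_iter) {
  K <- spec$kinship[[1]]
  rec <- sort(unique(pd$obs$i))
  Ksub <- K$values[rec, rec, drop = FALSE]
  ord <- order(pd$obs$i)
  y <- pd$obs$y[ord][match(rec, pd$obs$i[ord])]
  X <- matrix(1, length(rec), 1)
  ini <- if (!is.null(init))
    list(sigma2 = init$terms[[1]][1, 1], sigma2_e = init$resid[[1]][1, 1])
  else NULL
  fit <- emreml_spectral(y, X, Ksub, init = ini, tol = tol,
                         max_iter = max_iter)
  lab <- pd$keys$label
  vc <- list(terms = list(matrix(fit$sigma2, 1, 1, dimnames = list(lab, lab))),
             resid = setNames(list(matrix(fit$sigma2_e, 1, 1,
                                          dimnames = list(pd$traits, pd$traits))),
                              pd$sites))
  pidx <- param_index(pd, 1L)
  vcov <- fit$vcov
  dimnames(vcov) <- list(pidx$names, pidx$names)
  ai <- list(AI = tryCatch(solve(vcov), error = function(e) MASS::ginv(vcov)),
             vcov = vcov, pidx = pidx)
  new_varcomp(vc, pd, spec, fit$loglik, fit$converged, ai)
}

#' Solve the mixed-model equations for breeding values and their PEV
#'
#' Solves the MME at the supplied variance components and extracts, for
#' every individual in the relationship matrix and every response key, the
#' predicted genetic effect (breeding value, from the additive term) and
#' its prediction error variance (PEV), read from the corresponding
#' diagonal entries of the inverse coefficient matrix.
#'
#' @param spec a [model_spec()]
#' @param phenotypes adjusted [phenotype_table()]
#' @param varcomp an `op_varcomp` from [fit_reml()]
#' @return a `data.frame` (class `breeding_values`) with columns id, trait,
#'   site, bv, pev and attribute `"label"`
#' @export
predict_blup <- function(spec, phenotypes, varcomp) {
  pd <- prepare_model_data(spec, phenotypes)
  mme <- assemble_mme(spec, phenotypes, varcomp)
  chC <- tryCatch(chol(mme$C), error = function(e)
    stop("MME coefficient matrix is not positive definite; ",
         "blend the relationship matrix (blend_relmat) before fitting"))
  theta <- backsolve(chC, forwardsolve(t(chC), mme$rhs))
  Ci_diag <- diag(chol2inv(chC))
  off <- mme$layout$random_offset[["additive"]]
  out <- vector("list", pd$q)
  for (k in seq_len(pd$q)) {
    blk <- off + (k - 1L) * pd$n + seq_len(pd$n)
    out[[k]] <- data.frame(id = pd$ids,
                           trait = pd$keys$trait[k],
                           site = pd$keys$site[k],
                           bv = theta[blk],
                           pev = Ci_diag[blk],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "label") <- spec$label
  class(res) <- c("breeding_values", "data.frame")
  res
}

#' Fit a genetic evaluation model end to end
#'
#' Convenience wrapper: builds the [model_spec()], estimates variance
#' components with [fit_reml()] and predicts breeding values with
#' [predict_blup()].
#'
#' @inheritParams model_spec
#' @inheritParams fit_reml
#' @param phenotypes adjusted [phenotype_table()]
#' @return list with `spec`, `varcomp` and `bvs`
#' @export
fit_genetic_model <- function(phenotypes, kinship, traits, label = "GBLUP-A",
                              init = NULL, tol = 1e-8, max_iter = 2000L) {
  spec <- model_spec(traits, kinship, label = label)
  varcomp <- fit_reml(spec, phenotypes, init = init, tol = tol,
                      max_iter = max_iter)
  bvs <- predict_blup(spec, phenotypes, varcomp)
  list(spec = spec, varcomp = varcomp, bvs = bvs)
}

#' Stage-one adjustment: remove replication (block) effects
#'
#' First stage of the two-stage analysis. Each trait is analysed separately
#' within each site with an intercept, a random replication (block) effect
#' and, by default, a random pedigree-based additive effect (so block
#' predictions are not contaminated by family structure); the adjusted
#' phenotype is the raw value minus the predicted replication effect. Site
#' means are retained in the data.
#'
#' @param phenotypes raw [phenotype_table()]
#' @param pedigree recorded [pedigree_table()] covering all phenotyped
#'   individuals
#' @param genetic_term include the pedigree-based additive term in the
#'   stage-one model (recommended)
#' @param tol,max_iter EM-REML controls for the per-site-trait fits
#' @return the adjusted [phenotype_table()]
#' @export
adjust_stage1 <- function(phenotypes, pedigree, genetic_term = TRUE,
                          tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  A <- NULL
  if (genetic_term) {
    stopifnot(inherits(pedigree, "pedigree_table"))
    missing_ids <- setdiff(unique(phenotypes$id), pedigree$id)
    if (length(missing_ids))
      stop("phenotyped individual(s) absent from the pedigree: ",
           paste(head(missing_ids, 5), collapse = ", "))
    A <- build_A(pedigree)
  }
  out <- phenotypes
  for (s in unique(phenotypes$site)) {
    for (tr in unique(phenotypes$trait)) {
      at <- which(phenotypes$site == s & phenotypes$trait == tr)
      if (!length(at)) next
      reps <- sort(unique(phenotypes$rep[at]))
      if (length(reps) < 2L) {
        warning("site ", s, ", trait ", tr,
                ": single replication; no adjustment applied")
        next
      }
      y <- phenotypes$value[at]
      Zr <- outer(phenotypes$rep[at], reps, "==") * 1
      Zlist <- list(Zr)
      Klist <- list(NULL)
      if (genetic_term) {
        Zg <- matrix(0, length(at), length(A$ids))
        Zg[cbind(seq_along(at), match(phenotypes$id[at], A$ids))] <- 1
        Zlist <- c(Zlist, list(Zg))
        Klist <- c(Klist, list(A$values))
      }
      fit <- emreml_uni(y, matrix(1, length(at), 1), Zlist, Klist,
                        tol = tol, max_iter = max_iter)
      rep_eff <- fit$u[[1]]
      out$value[at] <- y - rep_eff[match(phenotypes$rep[at], reps)]
    }
  }
  out
}
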