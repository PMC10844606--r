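#' Narrow-sense heritability from fitted variance components
#'
#' For each trait, h2 = sigma2_a / (sigma2_a + sigma2_e) with both variances
#' averaged across sites (mean of the site-specific genetic variances and
#' mean of the site residual variances). For models with dominance and
#' epistatic terms the denominator also includes their (site-averaged)
#' variances. Standard errors are propagated from the average-information
#' covariance of the variance parameters by the delta method.
#'
#' @param varcomp an `op_varcomp` from [fit_reml()]
#' @return data.frame with columns trait, h2, se
#' @export
heritability <- function(varcomp) {
  stopifnot(inherits(varcomp, "op_varcomp"))
  keys <- varcomp$keys
  ns <- length(varcomp$sites)
  pn <- names(varcomp$params)
  term_names <- names(varcomp$terms)
  out <- data.frame(trait = varcomp$traits, h2 = NA_real_, se = NA_real_,
                    stringsAsFactors = FALSE)
  for (ti in seq_along(varcomp$traits)) {
    tr <- varcomp$traits[ti]
    kt <- which(keys$trait == tr)
    # weight vector over the parameter vector for each variance pool
    w_gen <- setNames(numeric(length(pn)), pn)   # additive
    w_oth <- w_gen                               # dominance + epistatic
    w_res <- w_gen
    for (t in seq_along(term_names)) {
      for (k in kt) {
        nm <- sprintf("Sg%d.%s:%s", t, keys$label[k], keys$label[k])
        if (term_names[t] == "additive") w_gen[nm] <- w_gen[nm] + 1 / ns
        else w_oth[nm] <- w_oth[nm] + 1 / ns
      }
    }
    for (s in varcomp$sites) {
      nm <- sprintf("R.%s.%s:%s", s, tr, tr)
      w_res[nm] <- w_res[nm] + 1 / ns
    }
    va <- sum(w_gen * varcomp$params)
    vo <- sum(w_oth * varcomp$params)
    ve <- sum(w_res * varcomp$params)
    if (va < 0 || ve < 0)
      stop("negative variance estimate for trait ", tr)
    tot <- va + vo + ve
    h2 <- va / tot
    grad <- w_gen / tot - va * (w_gen + w_oth + w_res) / tot^2
    se <- sqrt(max(drop(t(grad) %*% varcomp$vcov_params %*% grad), 0))
    out$h2[ti] <- h2
    out$se[ti] <- se
  }
  out
}

#' Theoretical accuracy of predicted breeding values
#'
#' TA_i = sqrt(1 - PEV_i / sigma2_a), per individual and response key, with
#' sigma2_a the additive genetic variance of that (trait, site). PEV above
#' sigma2_a (possible under blending) is clamped to it, giving accuracy 0
#' rather than an imaginary number; a warning reports how many values were
#' clamped.
#'
#' @param bvs a `breeding_values` data.frame from [predict_blup()]
#' @param varcomp the matching `op_varcomp`
#' @return data.frame id, trait, site, ta
#' @export
theoretical_accuracy <- function(bvs, varcomp) {
  stopifnot(inherits(bvs, "breeding_values"), inherits(varcomp, "op_varcomp"))
  lab <- paste0(bvs$trait, "@", bvs$site)
  sa <- diag(varcomp$terms[["additive"]])[match(lab, varcomp$keys$label)]
  if (anyNA(sa)) stop("breeding values and variance components use different keys")
  if (any(sa <= 0)) stop("additive variance is zero; accuracy undefined")
  ratio <- bvs$pev / sa
  n_clamp <- sum(ratio > 1)
  if (n_clamp > 0)
    warning(n_clamp, " PEV value(s) exceeded the additive variance; ",
            "accuracy clamped to 0")
  data.frame(id = bvs$id, trait = bvs$trait, site = bvs$site,
             ta = sqrt(pmax(1 - ratio, 0)), stringsAsFactors = FALSE)
}

#' Expected genetic gain of truncation selection
#'
#' Percentage gain of selecting the `n_top` individuals with the highest
#' site-averaged breeding values for a trait: 100 * mean(selected BV) /
#' trait mean.
#'
#' @param bvs a `breeding_values` data.frame
#' @param trait trait name
#' @param n_top number of individuals selected
#' @param trait_mean base-population trait mean (same units as the BVs)
#' @param ids optional candidate set (defaults to all ids in `bvs`)
#' @return gain in percent
#' @export
expected_gain <- function(bvs, trait, n_top, trait_mean, ids = NULL) {
  if (!trait %in% bvs$trait) stop("trait '", trait, "' absent from bvs")
  if (trait_mean == 0) stop("trait_mean must be non-zero")
  sb <- site_average_bv(bvs, trait)
  if (!is.null(ids)) sb <- sb[names(sb) %in% ids]
  if (n_top > length(sb)) stop("n_top exceeds the number of candidates")
  sel <- sort(sb, decreasing = TRUE)[seq_len(n_top)]
  100 * mean(sel) / trait_mean
}

# site-averaged breeding value per individual for one trait
site_average_bv <- function(bvs, trait) {
  b <- bvs[bvs$trait == trait, , drop = FALSE]
  tapply(b$bv, b$id, mean)
}

#' Group co-ancestry of a contribution vector
#'
#' Returns c' K c / 2 for contributions c (non-negative, summing to 1) under
#' relationship matrix K, together with the mean pairwise relationship among
#' contributing individuals (the off-diagonal mean of K restricted to the
#' support of c), which is the scale the co-ancestry limits 0.25 (half-sib)
#' and 0.125 sit on.
#'
#' @param contrib named numeric contribution vector (names = ids) or a
#'   numeric vector aligned with `K$ids`
#' @param K a [relmat()]
#' @return list with `group` (c'Kc/2) and `mean_pairwise`
#' @export
group_coancestry <- function(contrib, K) {
  stopifnot(inherits(K, "relmat"))
  if (!is.null(names(contrib))) {
    idx <- match(names(contrib), K$ids)
    if (anyNA(idx)) stop("contribution ids absent from K")
    c_full <- numeric(length(K$ids))
    c_full[idx] <- contrib
  } else {
    if (length(contrib) != length(K$ids))
      stop("contribution vector does not match K dimension")
    c_full <- contrib
  }
  if (any(c_full < 0) || abs(sum(c_full) - 1) > 1e-8)
    stop("contributions must be non-negative and sum to 1")
  sel <- which(c_full > 0)
  V <- K$values[sel, sel, drop = FALSE]
  mp <- if (length(sel) > 1L) mean(V[upper.tri(V)]) else 0
  list(group = drop(crossprod(c_full, K$values %*% c_full)) / 2,
       mean_pairwise = mp)
}

#' Configuration for optimum contribution selection
#'
#' @param n_max maximum number of selected individuals (equal contributions
#'   1/N; the optimizer may select fewer when constraints make that optimal)
#' @param delta_f_limit co-ancestry ceiling, or NULL for unconstrained
#' @param coancestry which co-ancestry definition the ceiling applies to:
#'   "mean_pairwise" (off-diagonal mean of K among selected; the scale on
#'   which 0.25 = half-sibs) or "group" (c'Kc/2)
#' @param constraints list of auxiliary constraints, each
#'   `list(trait =, dir = ">="|"<=", bound =)` on the mean breeding value of
#'   the selected set (e.g. no wood-density loss: WD >= 0)
#' @param standardize standardize per-trait BVs to unit variance before
#'   forming the composite objective; default TRUE when more than one
#'   objective trait
#' @param exact_limit maximum candidate count for the exact branch-and-bound
#' @param restarts,seed heuristic randomized restarts and seed
#' @return an `ocs_config` list
#' @export
ocs_config <- function(n_max = 30, delta_f_limit = NULL,
                       coancestry = c("mean_pairwise", "group"),
                       constraints = list(), standardize = NULL,
                       exact_limit = 25, restarts = 50, seed = 1L) {
  coancestry <- match.arg(coancestry)
  stopifnot(n_max >= 1, is.null(delta_f_limit) || delta_f_limit >= 0)
  structure(list(n_max = as.integer(n_max), delta_f_limit = delta_f_limit,
                 coancestry = coancestry, constraints = constraints,
                 standardize = standardize, exact_limit = exact_limit,
                 restarts = restarts, seed = as.integer(seed)),
            class = "ocs_config")
}

#' Optimum contribution selection
#'
#' Selects up to `n_max` individuals with equal contributions 1/N to
#' maximize the total (equally weighted, optionally standardized) breeding
#' value of the selected set over the objective traits, subject to a
#' co-ancestry ceiling and auxiliary mean-BV constraints (e.g. no
#' wood-density loss). Small candidate sets are solved exactly by
#' branch-and-bound over subsets (with an optimality certificate); larger
#' ones by a deterministic greedy construction with pairwise-swap local
#' search and randomized restarts. The reported gain per trait is the mean
#' raw breeding value of the selected set.
#'
#' @param bvs a `breeding_values` data.frame or a matrix/data.frame with one
#'   column per trait and ids as rownames
#' @param K a [relmat()] covering the candidates
#' @param config an [ocs_config()]
#' @param objective_traits traits entering the objective
#' @return an `ocs_solution`: selected ids, contribution vector, per-trait
#'   gains, achieved co-ancestry (both definitions), solver and optimality
#'   flag; or a feasible = FALSE report when constraints cannot be met
#' @export
ocs_optimize <- function(bvs, K, config = ocs_config(),
                         objective_traits = NULL) {
  stopifnot(inherits(K, "relmat"), inherits(config, "ocs_config"))
  if (inherits(bvs, "breeding_values")) {
    traits <- unique(bvs$trait)
    bmat <- sapply(traits, function(tr) {
      sb <- site_average_bv(bvs, tr)
      sb[match(K$ids, names(sb))]
    })
    bmat <- matrix(bmat, nrow = length(K$ids), dimnames = list(K$ids, traits))
  } else {
    bmat <- as.matrix(bvs)
    if (is.null(rownames(bmat))) stop("bvs needs ids as rownames")
    bmat <- bmat[match(K$ids, rownames(bmat)), , drop = FALSE]
  }
  if (anyNA(bmat)) stop("breeding values missing for some candidates in K")
  if (is.null(objective_traits)) objective_traits <- colnames(bmat)
  if (!all(objective_traits %in% colnames(bmat)))
    stop("objective trait(s) absent from bvs")
  standardize <- config$standardize
  if (is.null(standardize)) standardize <- length(objective_traits) > 1L
  obj <- bmat[, objective_traits, drop = FALSE]
  if (standardize) obj <- scale(obj)
  score <- unname(rowSums(obj))

  V <- K$values
  n <- length(score)
  cons <- config$constraints
  cmat <- if (length(cons))
    sapply(cons, function(cc) bmat[, cc$trait]) else NULL
  feas <- function(sel) {
    N <- length(sel)
    if (N == 0L) return(FALSE)
    if (!is.null(config$delta_f_limit)) {
      df <- if (config$coancestry == "mean_pairwise") {
        if (N > 1L) (sum(V[sel, sel]) - sum(diag(V)[sel])) / (N * (N - 1L)) else 0
      } else sum(V[sel, sel]) / (2 * N^2)
      if (df > config$delta_f_limit + 1e-12) return(FALSE)
    }
    if (!is.null(cmat)) {
      for (ci in seq_along(cons)) {
        m <- mean(cmat[sel, ci])
        ok <- if (cons[[ci]]$dir == ">=") m >= cons[[ci]]$bound - 1e-12
        else m <= cons[[ci]]$bound + 1e-12
        if (!ok) return(FALSE)
      }
    }
    TRUE
  }

  if (n <= config$exact_limit) {
    sol <- ocs_exact(score, feas, config$n_max)
    solver <- "exact"
  } else {
    sol <- ocs_heuristic(score, feas, config$n_max, config$restarts,
                         config$seed)
    solver <- "heuristic"
  }
  if (is.null(sol)) {
    return(structure(list(feasible = FALSE, selected = character(0),
                          solver = solver,
                          message = "no feasible selection under the constraints"),
                     class = "ocs_solution"))
  }
  sel <- sol$sel
  ids <- K$ids[sel]
  contrib <- setNames(rep(1 / length(sel), length(sel)), ids)
  co <- group_coancestry(contrib, K)
  gains <- colMeans(bmat[sel, , drop = FALSE])
  structure(list(feasible = TRUE, selected = ids, contributions = contrib,
                 n_selected = length(sel), objective = sol$obj,
                 gain = gains,
                 coancestry_group = co$group,
                 coancestry_mean_pairwise = co$mean_pairwise,
                 solver = solver,
                 optimal = identical(solver, "exact")),
            class = "ocs_solution")
}

#' @export
print.ocs_solution <- function(x, ...) {
  if (!x$feasible) {
    cat("OCS: infeasible --", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("OCS (%s%s): %d selected, mean pairwise kinship %.4f\n",
              x$solver, if (x$optimal) ", optimal" else "",
              x$n_selected, x$coancestry_mean_pairwise))
  cat("  gains:", paste(sprintf("%s %.3f", names(x$gain), x$gain),
                        collapse = ", "), "\n")
  invisible(x)
}

# exact branch-and-bound over subsets; candidates visited in decreasing
# score order, bound = current sum + best possible completion
ocs_exact <- function(score, feas, n_max) {
  ord <- order(-score)
  s <- score[ord]
  n <- length(s)
  pos_s <- pmax(s, 0)
  # suffix table of the largest k positive scores from position i on
  best <- new.env(parent = emptyenv())
  best$obj <- -Inf; best$sel <- NULL
  rec <- function(i, sel, cur) {
    if (length(sel) && feas(ord[sel]) && cur > best$obj) {
      best$obj <- cur; best$sel <- ord[sel]
    }
    if (i > n || length(sel) >= n_max) return(invisible())
    cap <- n_max - length(sel)
    rem <- pos_s[i:n]
    bound <- cur + sum(sort(rem, decreasing = TRUE)[seq_len(min(cap, length(rem)))])
    if (bound <= best$obj + 1e-12) return(invisible())
    rec(i + 1L, c(sel, i), cur + s[i])
    rec(i + 1L, sel, cur)
  }
  rec(1L, integer(0), 0)
  if (is.null(best$sel)) NULL else list(sel = best$sel, obj = best$obj)
}

# greedy construction + first-improvement swap/add local search with
# randomized restarts (deterministic given the seed)
ocs_heuristic <- function(score, feas, n_max, restarts, seed) {
  n <- length(score)
  improve <- function(sel) {
    obj <- sum(score[sel])
    repeat {
      moved <- FALSE
      out <- setdiff(order(-score), sel)
      # add
      if (length(sel) < n_max) {
        for (j in out) {
          if (score[j] > 0 && feas(c(sel, j))) {
            sel <- c(sel, j); obj <- obj + score[j]; moved <- TRUE
            out <- setdiff(out, j)
            if (length(sel) >= n_max) break
          }
        }
      }
      # swap lowest-score members for better outsiders
      for (i in sel[order(score[sel])]) {
        for (j in out) {
          if (score[j] > score[i] && feas(c(setdiff(sel, i), j))) {
            sel <- c(setdiff(sel, i), j)
            obj <- obj + score[j] - score[i]
            out <- c(setdiff(out, j), i)
            moved <- TRUE
            break
          }
        }
      }
      if (!moved) break
    }
    list(sel = sel, obj = sum(score[sel]))
  }
  greedy <- function(noise) {
    sel <- integer(0)
    cand <- order(-score)
    for (step in seq_len(n_max)) {
      ok <- Filter(function(j) score[j] > 0 && feas(c(sel, j)),
                   setdiff(cand, sel))
      if (!length(ok)) break
      pick <- if (noise && length(ok) > 1L)
        ok[sample.int(min(3L, length(ok)), 1L)] else ok[[1L]]
      sel <- c(sel, pick)
    }
    sel
  }
  best <- NULL
  with_sim_rng(seed, {
    for (r in seq_len(max(1L, restarts))) {
      sel0 <- greedy(noise = r > 1L)
      if (!length(sel0)) next
      cand <- improve(sel0)
      if (length(cand$sel) && feas(cand$sel) &&
          (is.null(best) || cand$obj > best$obj)) best <- cand
    }
  })
  best
}
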