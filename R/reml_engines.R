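# Internal EM-REML engines.
#
# Two engines share the same algorithm (Henderson's mixed-model-equation
# EM-REML, the expectation-conditional-maximization form): a dense
# general-purpose one for arbitrary scalar-variance random terms, and a
# spectral one for the frequent special case of a single genetic term with
# one record per individual, where an eigendecomposition of the relationship
# matrix makes every iteration O(n).

# Dense univariate EM-REML.
# y: response (length N); X: fixed-effect design (N x p);
# Zlist: list of incidence matrices (N x q_t); Klist: parallel list of
# q_t x q_t covariance structures (NULL = identity).
# Returns variance components, BLUP solutions and the restricted
# log-likelihood trace.
emreml_uni <- function(y, X, Zlist, Klist = NULL, init = NULL,
                       tol = 1e-8, max_iter = 1000L) {
  N <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  nt <- length(Zlist)
  if (is.null(Klist)) Klist <- vector("list", nt)
  q <- vapply(Zlist, ncol, integer(1))
  Kinv <- vector("list", nt)
  logdetK <- numeric(nt)
  for (t in seq_len(nt)) {
    if (is.null(Klist[[t]])) {
      logdetK[t] <- 0
    } else {
      ch <- chol(Klist[[t]])
      Kinv[[t]] <- chol2inv(ch)
      logdetK[t] <- 2 * sum(log(diag(ch)))
    }
  }
  Tm <- do.call(cbind, c(list(X), lapply(Zlist, as.matrix)))
  d <- ncol(Tm)
  idx <- vector("list", nt)
  off <- p
  for (t in seq_len(nt)) {
    idx[[t]] <- off + seq_len(q[t])
    off <- off + q[t]
  }
  TtT <- crossprod(Tm)
  Tty <- crossprod(Tm, y)
  yy <- sum(y^2)

  vy <- stats::var(y)
  s2 <- if (is.null(init)) rep(vy / (2 * nt), nt) else init$sigma2
  se <- if (is.null(init)) vy / 2 else init$sigma2_e
  floor_v <- 1e-10 * max(vy, 1e-12)

  ll_trace <- numeric(0)
  converged <- FALSE
  theta <- NULL; Ci <- NULL
  for (iter in seq_len(max_iter)) {
    C <- TtT / se
    for (t in seq_len(nt)) {
      blk <- idx[[t]]
      if (is.null(Kinv[[t]])) {
        C[cbind(blk, blk)] <- C[cbind(blk, blk)] + 1 / s2[t]
      } else {
        C[blk, blk] <- C[blk, blk] + Kinv[[t]] / s2[t]
      }
    }
    ch <- chol(C)
    theta <- backsolve(ch, forwardsolve(t(ch), Tty / se))
    Ci <- chol2inv(ch)
    logdetC <- 2 * sum(log(diag(ch)))
    yPy <- (yy - sum(theta * Tty)) / se
    ll <- -0.5 * (N * log(se) +
                    sum(q * log(s2)) + sum(logdetK) +
                    logdetC + yPy)
    ll_trace <- c(ll_trace, ll)
    # EM updates
    for (t in seq_len(nt)) {
      blk <- idx[[t]]
      u <- theta[blk]
      if (is.null(Kinv[[t]])) {
        s2[t] <- max((sum(u^2) + sum(diag(Ci)[blk])) / q[t], floor_v)
      } else {
        s2[t] <- max((drop(crossprod(u, Kinv[[t]] %*% u)) +
                        sum(Kinv[[t]] * Ci[blk, blk])) / q[t], floor_v)
      }
    }
    ehat <- y - drop(Tm %*% theta)
    trTCT <- sum(Tm * (Tm %*% Ci))
    se <- max((sum(ehat^2) + trTCT) / N, floor_v)
    if (iter > 1L) {
      dll <- ll_trace[iter] - ll_trace[iter - 1L]
      if (abs(dll) / (abs(ll_trace[iter]) + 1) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(sigma2 = s2, sigma2_e = se,
       beta = theta[seq_len(p)],
       u = lapply(seq_len(nt), function(t) theta[idx[[t]]]),
       loglik = ll_trace, converged = converged, n_iter = length(ll_trace))
}

# Spectral EM-REML for y = X beta + u + e with u ~ N(0, s2a * K),
# one record per individual (obs i corresponds to row i of K).
# Exactly the same EM fixed point as the dense engine, but each iteration is
# O(N p^2) after a single eigendecomposition of K.
emreml_spectral <- function(y, X, K, init = NULL, tol = 1e-8,
                            max_iter = 2000L) {
  N <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-10)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  vy <- stats::var(y)
  s2a <- if (is.null(init)) vy / 2 else init$sigma2
  se <- if (is.null(init)) vy / 2 else init$sigma2_e
  floor_v <- 1e-10 * max(vy, 1e-12)

  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    v <- s2a * lam + se
    XtV <- Xt / v
    Sg <- crossprod(Xt, XtV)                 # X' V^-1 X
    beta <- solve(Sg, crossprod(XtV, yt))
    r <- yt - drop(Xt %*% beta)
    ll <- -0.5 * (sum(log(v)) + determinant(Sg, logarithm = TRUE)$modulus +
                    sum(r^2 / v))
    ll_trace <- c(ll_trace, ll)
    # MME quantities in the rotated basis
    a <- 1 / se
    dvec <- a + 1 / (s2a * lam)
    S <- a * crossprod(Xt) - a^2 * crossprod(Xt, Xt / dvec)
    Sinv <- solve(S)
    bmme <- drop(Sinv %*% (a * crossprod(Xt, yt) -
                             a^2 * crossprod(Xt, yt / dvec)))
    u <- a * (yt - drop(Xt %*% bmme)) / dvec
    ti <- rowSums((Xt %*% Sinv) * Xt)        # x_i' S^-1 x_i
    cuu <- 1 / dvec + a^2 * ti / dvec^2
    s2a <- max((sum(u^2 / lam) + sum(cuu / lam)) / N, floor_v)
    ehat <- yt - drop(Xt %*% bmme) - u
    trTCT <- sum(1 / dvec + ti * (1 - a / dvec)^2)
    se <- max((sum(ehat^2) + trTCT) / N, floor_v)
    if (iter > 1L) {
      dll <- ll_trace[iter] - ll_trace[iter - 1L]
      if (abs(dll) / (abs(ll_trace[iter]) + 1) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  # one AI round for the 2x2 information of (s2a, se)
  v <- s2a * lam + se
  XtV <- Xt / v
  Sg <- crossprod(Xt, XtV)
  beta <- solve(Sg, crossprod(XtV, yt))
  r <- yt - drop(Xt %*% beta)
  Py <- r / v
  Pf <- function(f) {
    f / v - (Xt %*% solve(Sg, crossprod(Xt, f / v))) / v
  }
  fa <- lam * Py
  fe <- Py
  AI <- matrix(0, 2, 2)
  Pfa <- Pf(fa); Pfe <- Pf(fe)
  AI[1, 1] <- 0.5 * sum(fa * Pfa)
  AI[1, 2] <- AI[2, 1] <- 0.5 * sum(fa * Pfe)
  AI[2, 2] <- 0.5 * sum(fe * Pfe)
  vc <- tryCatch(solve(AI), error = function(e) MASS::ginv(AI))
  list(sigma2 = s2a, sigma2_e = se,
       se_sigma2 = sqrt(pmax(diag(vc), 0))[1],
       se_sigma2_e = sqrt(pmax(diag(vc), 0))[2],
       vcov = vc,
       loglik = ll_trace, converged = converged, n_iter = length(ll_trace))
}
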