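# EM-REML on Henderson's mixed-model equations.
#
# Model: y = X b + sum_i Z_i u_i + e, u_i ~ N(0, sigma2_i I), e ~ N(0,
# sigma2_e I). The coefficient matrix is
#   M = [X'X  X'Z; Z'X  Z'Z + diag(lambda_i)],  lambda_i = sigma2_e/sigma2_i,
# and the EM updates are the classical Henderson forms
#   sigma2_i <- (u_i'u_i + sigma2_e tr(Cinv_ii)) / q_i
#   sigma2_e <- (y'y - b'X'y - u'Z'y) / (n - rank(X)),
# which keep every component non-negative and increase the REML
# log-likelihood monotonically. Variances pinned near zero are held at a
# floor so lambda stays finite.

emreml <- function(y, X, Zlist, tol = 1e-8, max_iter = 500L,
                   var_floor = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  q <- vapply(Zlist, ncol, integer(1L))
  nr <- length(Zlist)
  Zall <- do.call(cbind, Zlist)
  XtX <- crossprod(X)
  XtZ <- crossprod(X, Zall)
  ZtZ <- crossprod(Zall)
  Xty <- crossprod(X, y)
  Zty <- crossprod(Zall, y)
  yty <- sum(y^2)
  rhs <- c(Xty, Zty)
  rankX <- qr(X)$rank
  zblk <- split(seq_len(sum(q)), rep(seq_len(nr), q))

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  s2 <- rep(vy / (2 * max(nr, 1L)), nr)
  s2e <- vy / 2
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  sol <- NULL
  Cinv <- NULL

  repeat {
    iter <- iter + 1L
    lambda <- s2e / pmax(s2, var_floor)
    M <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), ZtZ + diag(rep(lambda, q), sum(q))))
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (!is.null(ch)) {
      Cinv <- chol2inv(ch)
      ldM <- 2 * sum(log(diag(ch)))
    } else {
      Cinv <- MASS_ginv(M)
      ldM <- determinant(M, logarithm = TRUE)$modulus
    }
    sol <- Cinv %*% rhs
    uhat <- sol[p + seq_len(sum(q))]
    sse <- yty - sum(sol * rhs)
    s2e_new <- max(sse / (n - rankX), var_floor)
    s2_new <- vapply(seq_len(nr), function(i) {
      ui <- uhat[zblk[[i]]]
      tr <- sum(diag(Cinv)[p + zblk[[i]]])
      max((sum(ui^2) + s2e * tr) / q[i], var_floor)
    }, numeric(1L))

    # REML log-likelihood (up to a constant), from MME quantities
    ll <- -0.5 * ((n - rankX - sum(q)) * log(s2e) + sum(q * log(pmax(s2, var_floor))) +
                    ldM + sse / s2e)
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L) {
      rel <- abs(ll - ll_trace[iter - 1L]) / (abs(ll_trace[iter - 1L]) + 1e-10)
      if (rel < tol) {
        # keep the components that produced the final solve so beta/u/Cinv
        # and the reported variances are mutually consistent
        converged <- TRUE
        break
      }
    }
    s2 <- s2_new
    s2e <- s2e_new
    if (iter >= max_iter) break
  }

  beta <- sol[seq_len(p)]
  names(beta) <- colnames(X)
  u <- lapply(seq_len(nr), function(i) {
    ui <- sol[p + zblk[[i]]]
    names(ui) <- colnames(Zlist[[i]])
    ui
  })
  names(u) <- names(Zlist)
  names(s2) <- names(Zlist)
  list(beta = beta, u = u, var_comp = s2, var_resid = s2e,
       Cinv = Cinv, p = p, zblk = lapply(zblk, function(ix) p + ix),
       loglik = ll_trace, converged = converged, n_iter = iter,
       rankX = rankX)
}

# Minimal Moore-Penrose fallback for a singular coefficient matrix.
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1L]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Incidence matrix for a factor, one column per level.
inc_matrix <- function(f) {
  f <- factor(f)
  M <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  M[cbind(seq_along(f), as.integer(f))] <- 1
  M
}
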