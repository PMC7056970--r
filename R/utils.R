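#' @keywords internal
"_PACKAGE"

#' Derive a deterministic sub-stream seed
#'
#' One user-facing seed drives every stage of a simulation or analysis;
#' each stage or repeat derives its own 32-bit seed from it, so a full run
#' is reproducible from a single integer without reusing RNG streams.
#'
#' @param seed master integer seed.
#' @param offset stage or repeat index.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483629)
}

# Symmetric matrix square root via eigendecomposition; tolerates PSD inputs
# where chol() would fail. Negative eigenvalues below -tol are an error.
sym_sqrt <- function(S, tol = 1e-8) {
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  if (any(ee$values < -tol * max(abs(ee$values), 1)))
    stop("matrix is not positive semi-definite")
  d <- pmax(ee$values, 0)
  ee$vectors %*% (sqrt(d) * t(ee$vectors))
}

# Clip eigenvalues to make a correlation-like matrix positive definite,
# then restore the unit diagonal.
make_pd_corr <- function(R, min_eig = 0.05) {
  ee <- eigen((R + t(R)) / 2, symmetric = TRUE)
  d <- pmax(ee$values, min_eig)
  S <- ee$vectors %*% (d * t(ee$vectors))
  D <- 1 / sqrt(diag(S))
  out <- S * tcrossprod(D)
  dimnames(out) <- dimnames(R)
  out
}

is_symmetric_psd <- function(S, tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) return(FALSE)
  if (max(abs(S - t(S))) > tol * max(abs(S), 1)) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}

# Draw from a scaled inverse chi-squared distribution:
# X ~ (df * scale + SS) / chisq(df + n) when used as a conjugate update.
rscinvchisq <- function(df, scale_x_df) {
  scale_x_df / stats::rchisq(1L, df = df)
}

# Row-wise cumulative sum mod 2 (crossover bookkeeping along a chromosome).
row_cumsum_mod2 <- function(M) {
  if (ncol(M) == 1L) return(M %% 2L)
  t(apply(M, 1L, cumsum)) %% 2L
}
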