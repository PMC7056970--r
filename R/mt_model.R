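# Multi-trait Bayesian GBLUP: y_it = mu_t + u_it + e_it with
# vec(U) ~ MVN(0, Sigma (x) K) and residuals independent across traits
# (R diagonal). Missing phenotype entries are data-augmented, which is what
# makes CV1 and CV2 pure masking patterns over one code path.

# Wide line x trait phenotype matrix for a trait set at one scope.
blues_matrix <- function(blues, traits, lines, scope = "ALL") {
  Y <- matrix(NA_real_, length(lines), length(traits),
              dimnames = list(lines, traits))
  for (tr in traits) {
    v <- blues_vector(blues, tr, scope)
    common <- intersect(lines, names(v))
    Y[common, tr] <- v[common]
  }
  Y
}

#' Multi-trait Bayesian GBLUP by Gibbs sampling
#'
#' Gibbs sampler for the multivariate Gaussian model with unstructured
#' genetic covariance \code{Sigma} (Kronecker with the kinship K) and
#' diagonal residual covariance R. Full conditionals per iteration:
#' missing phenotypes from their conditional normal (data augmentation);
#' genetic values jointly across traits in the eigenbasis of K (the t x t
#' per-eigencomponent solves are batched through a simultaneous
#' diagonalization of Sigma against R, so the update is a handful of dense
#' matrix products); \code{Sigma} from its inverse-Wishart conditional
#' (or per-trait scaled-inverse-chi-squared when \code{diag_sigma});
#' each R element from a scaled-inverse-chi-squared; intercepts from
#' flat-prior normals. Posterior means are averaged over post-burn-in draws;
#' imputed phenotypes are accumulated Rao-Blackwellized (as \code{mu + U}
#' per draw) to cut Monte Carlo error.
#'
#' @param blues a \code{blue_table} covering the traits at \code{scope}.
#' @param traits character vector (>= 2) of trait names to fit jointly.
#' @param K a \code{kinship_matrix}; its line order defines the fit.
#' @param cfg a [gibbs_config()].
#' @param mask optional logical line x trait matrix, TRUE = phenotype enters
#'   the likelihood. Defaults to "observed wherever a BLUE exists"; entries
#'   masked FALSE or missing from the table are augmented.
#' @param scope scope label of the BLUEs.
#' @param fix_Sigma,fix_R,fix_mu fix parameters instead of sampling them
#'   (used by the closed-form oracle cross-checks).
#' @param diag_sigma constrain Sigma to a diagonal matrix (off-diagonal
#'   updates disabled); the fit then decomposes into independent
#'   single-trait models.
#' @return list of class \code{mt_fit}: \code{U_hat} (line x trait posterior
#'   means), \code{mu_hat}, \code{Sigma_hat}, \code{R_hat},
#'   \code{imputed_Y}, chain summaries and the effective mask.
#' @export
fit_mt <- function(blues, traits, K, cfg = gibbs_config(), mask = NULL,
                   scope = "ALL", fix_Sigma = NULL, fix_R = NULL,
                   fix_mu = NULL, diag_sigma = FALSE) {
  if (length(traits) < 2L) stop("multi-trait model needs >= 2 traits")
  lines <- rownames(K)
  n <- length(lines)
  t <- length(traits)
  Y0 <- blues_matrix(blues, traits, lines, scope)
  if (is.null(mask)) mask <- !is.na(Y0)
  if (!all(dim(mask) == c(n, t))) stop("mask dimensions must match lines x traits")
  obs <- mask & !is.na(Y0)
  n_obs_tr <- colSums(obs)
  if (any(n_obs_tr < 5L))
    stop("every trait must be observed for >= 5 lines; short: ",
         paste(traits[n_obs_tr < 5L], collapse = ", "))

  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(eg$values))
    stop("K is not positive semi-definite; apply a diagonal jitter")
  d <- pmax(eg$values, 1e-8)
  V <- eg$vectors
  Vt <- t(V)

  # observed-data moments for initialization and priors
  mu0 <- vapply(seq_len(t), function(j) mean(Y0[obs[, j], j]), numeric(1L))
  vph <- vapply(seq_len(t), function(j) stats::var(Y0[obs[, j], j]), numeric(1L))
  vph[!is.finite(vph) | vph <= 0] <- 1e-8
  nu0 <- cfg$prior_df
  nu_S <- t + 2
  S0 <- diag(0.5 * vph, t)
  S0R <- vph * 0.5 * (nu0 + 2) / nu0

  set.seed(cfg$seed)
  mu <- if (is.null(fix_mu)) mu0 else fix_mu
  Sigma <- if (is.null(fix_Sigma)) diag(0.5 * vph, t) else fix_Sigma
  Rv <- if (is.null(fix_R)) 0.5 * vph else fix_R
  U <- matrix(0, n, t)
  Y <- Y0
  Y[!obs] <- rep(mu, each = n)[!obs]

  keep <- seq(cfg$burn_in + 1L, cfg$n_iter, by = cfg$thin)
  n_keep <- length(keep)
  U_sum <- matrix(0, n, t)
  Yimp_sum <- matrix(0, n, t)
  mu_sum <- rep(0, t)
  Sigma_sum <- matrix(0, t, t)
  R_sum <- rep(0, t)
  Sigma_draws <- array(NA_real_, c(t, t, n_keep))
  cor_draws <- if (t >= 2L) numeric(n_keep) else NULL
  sigma_jitter_count <- 0L
  ki <- 0L

  for (it in seq_len(cfg$n_iter)) {
    # (a) augment missing phenotypes
    if (any(!obs)) {
      mu_mat <- matrix(mu, n, t, byrow = TRUE)
      sd_mat <- matrix(sqrt(Rv), n, t, byrow = TRUE)
      prop <- mu_mat + U + sd_mat * matrix(stats::rnorm(n * t), n, t)
      Y[!obs] <- prop[!obs]
    }

    # (b) joint eigenbasis update of the genetic values
    Yc <- sweep(Y, 2L, mu)
    Yt <- Vt %*% Yc
    Rs <- sqrt(Rv)
    Bmat <- t(t(Sigma) / Rs) / Rs          # R^-1/2 Sigma R^-1/2
    eS <- eigen((Bmat + t(Bmat)) / 2, symmetric = TRUE)
    theta <- pmax(eS$values, 1e-10)
    P <- eS$vectors
    Z <- Yt %*% (P / Rs)                   # rows: P' R^-1/2 ytilde_i
    Wmat <- outer(d, theta) / (1 + outer(d, theta))
    Bdraw <- Wmat * Z + sqrt(Wmat) * matrix(stats::rnorm(n * t), n, t)
    A <- Bdraw %*% t(P * Rs)               # back-transform R^1/2 P b_i
    U <- V %*% A

    # (c) Sigma | U  (inverse-Wishart, or per-trait chi-squared if diagonal)
    if (is.null(fix_Sigma)) {
      SS <- crossprod(A, A / d)
      if (diag_sigma) {
        Sigma <- diag(vapply(seq_len(t), function(j) {
          rscinvchisq(nu0 + n, nu0 * 0.5 * vph[j] * (nu0 + 2) / nu0 + SS[j, j])
        }, numeric(1L)), t)
      } else {
        repeat {
          Wdraw <- stats::rWishart(1L, nu_S + n, solve(S0 + SS))[, , 1L]
          Sig_new <- tryCatch(chol2inv(chol(Wdraw)), error = function(e) NULL)
          if (!is.null(Sig_new)) {
            Sigma <- (Sig_new + t(Sig_new)) / 2
            break
          }
          sigma_jitter_count <- sigma_jitter_count + 1L
          S0 <- S0 + diag(1e-8 * mean(vph), t)
        }
      }
    }

    # (d) residual variances and (e) intercepts
    E <- Y - matrix(mu, n, t, byrow = TRUE) - U
    if (is.null(fix_R)) {
      Rv <- vapply(seq_len(t), function(j) {
        rscinvchisq(nu0 + n, nu0 * S0R[j] + sum(E[, j]^2))
      }, numeric(1L))
    }
    if (is.null(fix_mu)) {
      mu <- colMeans(Y - U) + stats::rnorm(t, 0, sqrt(Rv / n))
    }

    if (it > cfg$burn_in && (it - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      ki <- ki + 1L
      U_sum <- U_sum + U
      Yimp_sum <- Yimp_sum + matrix(mu, n, t, byrow = TRUE) + U
      mu_sum <- mu_sum + mu
      Sigma_sum <- Sigma_sum + Sigma
      R_sum <- R_sum + Rv
      Sigma_draws[, , ki] <- Sigma
      if (!is.null(cor_draws))
        cor_draws[ki] <- Sigma[1L, 2L] / sqrt(Sigma[1L, 1L] * Sigma[2L, 2L])
    }
  }

  U_hat <- U_sum / ki
  dimnames(U_hat) <- list(lines, traits)
  imputed_Y <- Yimp_sum / ki
  dimnames(imputed_Y) <- dimnames(U_hat)
  Sigma_hat <- Sigma_sum / ki
  dimnames(Sigma_hat) <- list(traits, traits)
  structure(list(
    U_hat = U_hat,
    mu_hat = stats::setNames(mu_sum / ki, traits),
    Sigma_hat = Sigma_hat,
    R_hat = stats::setNames(R_sum / ki, traits),
    imputed_Y = imputed_Y,
    mask = obs,
    samples = list(gen_cor_12 = cor_draws, Sigma = Sigma_draws),
    sigma_jitter_count = sigma_jitter_count,
    traits = traits,
    config = cfg
  ), class = "mt_fit")
}

#' Posterior summary of a genetic correlation
#'
#' Summarizes the posterior of the genetic correlation between two traits of
#' a multi-trait fit on the Fisher-z scale: each retained draw's correlation
#' is transformed with atanh, averaged, and transformed back. Correlation
#' posteriors are skewed near the +/-1 boundaries, so this summary (close to
#' the posterior median) drifts less toward zero than the correlation of the
#' posterior-mean covariance matrix.
#'
#' @param fit an \code{mt_fit}.
#' @param i,j trait indices or names.
#' @return scalar correlation summary in (-1, 1).
#' @export
genetic_correlation <- function(fit, i = 1L, j = 2L) {
  S <- fit$samples$Sigma
  if (is.character(i)) i <- match(i, fit$traits)
  if (is.character(j)) j <- match(j, fit$traits)
  r <- S[i, j, ] / sqrt(S[i, i, ] * S[j, j, ])
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

#' Exact conditional means under the multi-trait Gaussian model
#'
#' Closed-form test oracle: builds the joint multivariate normal of all
#' line-by-trait phenotypes with covariance \code{Sigma (x) K + diag(R) (x)
#' I} and returns the exact conditional mean of the unobserved entries given
#' the observed ones, by direct linear solve. Feasible for n * t up to a few
#' thousand; parameters are taken as known, nothing is estimated.
#'
#' @param K kinship matrix (n x n).
#' @param Sigma trait genetic covariance (t x t).
#' @param R per-trait residual variances (length t).
#' @param Y_obs line x trait phenotype matrix (entries outside the mask are
#'   ignored).
#' @param mask logical line x trait matrix, TRUE = observed.
#' @param mu per-trait means (default 0).
#' @return line x trait matrix holding conditional means at masked-out
#'   entries and NA elsewhere.
#' @export
conditional_mean_oracle <- function(K, Sigma, R, Y_obs, mask, mu = NULL) {
  n <- nrow(K)
  t <- nrow(Sigma)
  if (is.null(mu)) mu <- rep(0, t)
  stopifnot(dim(Y_obs) == c(n, t), dim(mask) == c(n, t), length(R) == t)
  C <- kronecker(Sigma, unclass(K)) + kronecker(diag(R, t), diag(n))
  mvec <- rep(mu, each = n)
  o <- as.vector(mask)
  m <- !o
  if (!any(m)) stop("mask leaves nothing to predict")
  Coo <- C[o, o, drop = FALSE]
  Cmo <- C[m, o, drop = FALSE]
  yo <- as.vector(Y_obs)[o]
  sol <- tryCatch(solve(Coo, yo - mvec[o]), error = function(e)
    stop("singular joint covariance"))
  pred <- mvec[m] + as.vector(Cmo %*% sol)
  out <- matrix(NA_real_, n, t, dimnames = dimnames(Y_obs))
  out[m] <- pred
  out
}
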