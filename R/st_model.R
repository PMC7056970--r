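#' Configuration for the Gibbs samplers
#'
#' @param burn_in iterations discarded before averaging.
#' @param n_iter total iterations (burn-in included).
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param seed RNG seed for the chain.
#' @param prior_df degrees of freedom of the scaled-inverse-chi-squared
#'   variance priors.
#' @param prior_R2 fraction of the phenotypic variance assigned to the
#'   genetic prior scale (the remainder goes to the residual).
#' @return list of class \code{gibbs_config}.
#' @export
gibbs_config <- function(burn_in = 1500L, n_iter = 3000L, thin = 1L,
                         seed = 1L, prior_df = 5, prior_R2 = 0.5) {
  stopifnot(burn_in < n_iter, prior_df > 0, prior_R2 > 0, prior_R2 < 1,
            thin >= 1L)
  structure(list(burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df = prior_df, prior_R2 = prior_R2),
            class = "gibbs_config")
}

# Pull a named phenotype vector for one trait/scope out of a BLUE table.
blues_vector <- function(blues, trait, scope = "ALL") {
  d <- blues[blues$trait == trait & blues$scope == scope_label(scope), , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("trait '%s' not found in BLUE table", trait))
  stats::setNames(d$blue, d$line_id)
}

#' Single-trait Bayesian GBLUP by Gibbs sampling
#'
#' Fits \code{y = 1 mu + u + e} with \code{u ~ N(0, K sigma2_g)} and
#' \code{e ~ N(0, R sigma2_e)} (R the diagonal of optional per-observation
#' weights, identity by default). Sampling runs in the eigenbasis of the
#' observed-line block of K: a one-off rotation, then conjugate normal
#' updates for the transformed effects, scaled-inverse-chi-squared updates
#' for both variances and a flat-prior normal for the intercept. Genetic
#' values of unphenotyped lines are drawn each iteration from their exact
#' conditional normal given the observed-line effects, so predictions for
#' them are posterior means, not plug-ins.
#'
#' @param blues a \code{blue_table} (or anything [blues_vector()] accepts).
#' @param trait trait to fit.
#' @param K a \code{kinship_matrix} covering at least the observed lines.
#' @param cfg a [gibbs_config()].
#' @param observed_ids lines whose phenotype enters the likelihood; defaults
#'   to every line with a BLUE. Lines of K outside this set are predicted by
#'   augmentation.
#' @param scope scope label of the BLUEs to use.
#' @param weights optional per-observation precision weights (e.g.
#'   \code{1/se^2}); names must cover \code{observed_ids}.
#' @param fix_var_g,fix_var_e fix a variance at this value instead of
#'   sampling it (used by the closed-form BLUP cross-checks).
#' @return list of class \code{st_fit}: \code{u_hat} (all lines of K),
#'   \code{mu_hat}, \code{var_g_hat}, \code{var_e_hat}, chain summaries.
#' @export
fit_st <- function(blues, trait, K, cfg = gibbs_config(),
                   observed_ids = NULL, scope = "ALL", weights = NULL,
                   fix_var_g = NULL, fix_var_e = NULL) {
  y_all <- blues_vector(blues, trait, scope)
  lines <- rownames(K)
  if (is.null(observed_ids)) observed_ids <- intersect(lines, names(y_all))
  if (!all(observed_ids %in% lines)) stop("observed_ids not all present in K")
  if (!all(observed_ids %in% names(y_all))) stop("observed_ids lack BLUEs")
  n_obs <- length(observed_ids)
  if (n_obs < 10L) stop("need >= 10 observed lines")
  y <- unname(y_all[observed_ids])
  unobs <- setdiff(lines, observed_ids)

  Koo <- K[observed_ids, observed_ids, drop = FALSE]
  eg <- eigen(Koo, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(eg$values))
    stop("K is not positive semi-definite; apply a diagonal jitter")
  d <- pmax(eg$values, 0)
  pos <- d > 1e-10 * max(d)
  U <- eg$vectors
  w <- if (is.null(weights)) rep(1, n_obs) else unname(weights[observed_ids])
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive and finite")
  uniform_w <- max(w) - min(w) < 1e-12

  # conditional draw pieces for unobserved lines:
  # u_u | u_o ~ N(T u_o, sigma2_g * S),  T = K_uo K_oo^-1
  if (length(unobs) > 0L) {
    Kuo <- K[unobs, observed_ids, drop = FALSE]
    Koo_inv <- U %*% (ifelse(pos, 1 / d, 0) * t(U))
    Tmat <- Kuo %*% Koo_inv
    S0 <- K[unobs, unobs, drop = FALSE] - Tmat %*% t(Kuo)
    S0_sqrt <- sym_sqrt(S0, tol = 1e-6)
  }

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  nu0 <- cfg$prior_df
  S0g <- vy * cfg$prior_R2 * (nu0 + 2) / nu0 / mean(diag(Koo))
  S0e <- vy * (1 - cfg$prior_R2) * (nu0 + 2) / nu0

  set.seed(cfg$seed)
  mu <- mean(y)
  s2g <- if (is.null(fix_var_g)) max(vy * cfg$prior_R2, 1e-8) else fix_var_g
  s2e <- if (is.null(fix_var_e)) max(vy * (1 - cfg$prior_R2), 1e-8) else fix_var_e
  a <- rep(0, n_obs)

  keep <- seq(cfg$burn_in + 1L, cfg$n_iter, by = cfg$thin)
  n_keep <- length(keep)
  u_sum <- stats::setNames(rep(0, length(lines)), lines)
  u_sum_h1 <- u_sum
  mu_sum <- 0
  s2g_draws <- s2e_draws <- numeric(n_keep)
  ki <- 0L

  Ut <- t(U)
  for (it in seq_len(cfg$n_iter)) {
    if (uniform_w) {
      # diagonal eigenbasis update for the transformed effects
      yc <- Ut %*% (y - mu)
      v <- ifelse(pos, 1 / (w[1L] / s2e + 1 / (s2g * d)), 0)
      a <- as.vector(v * yc * w[1L] / s2e + sqrt(v) * stats::rnorm(n_obs))
    } else {
      # general weighted update: n x n precision solve
      P <- crossprod(U * sqrt(w)) / s2e + diag(ifelse(pos, 1 / (s2g * d), 1e12), n_obs)
      ch <- chol(P)
      mvec <- backsolve(ch, backsolve(ch, Ut %*% ((y - mu) * w) / s2e,
                                      transpose = TRUE))
      a <- as.vector(mvec + backsolve(ch, stats::rnorm(n_obs)))
    }
    u_obs <- as.vector(U %*% a)

    resid <- y - mu - u_obs
    mu <- sum(w * (y - u_obs)) / sum(w) +
      stats::rnorm(1L, 0, sqrt(s2e / sum(w)))
    if (is.null(fix_var_g)) {
      ssg <- sum(ifelse(pos, a^2 / d, 0))
      s2g <- rscinvchisq(nu0 + sum(pos), nu0 * S0g + ssg)
    }
    if (is.null(fix_var_e)) {
      resid <- y - mu - u_obs
      s2e <- rscinvchisq(nu0 + n_obs, nu0 * S0e + sum(w * resid^2))
    }

    if (it > cfg$burn_in && (it - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      ki <- ki + 1L
      u_full <- stats::setNames(rep(0, length(lines)), lines)
      u_full[observed_ids] <- u_obs
      if (length(unobs) > 0L) {
        u_full[unobs] <- as.vector(Tmat %*% u_obs) +
          sqrt(s2g) * as.vector(S0_sqrt %*% stats::rnorm(length(unobs)))
      }
      u_sum <- u_sum + u_full
      if (ki <= n_keep / 2) u_sum_h1 <- u_sum_h1 + u_full
      mu_sum <- mu_sum + mu
      s2g_draws[ki] <- s2g
      s2e_draws[ki] <- s2e
    }
  }

  u_hat <- u_sum / ki
  structure(list(
    u_hat = u_hat,
    mu_hat = mu_sum / ki,
    var_g_hat = mean(s2g_draws),
    var_e_hat = mean(s2e_draws),
    samples = list(var_g = s2g_draws, var_e = s2e_draws,
                   u_hat_first_half = u_sum_h1 / floor(ki / 2),
                   u_hat_second_half = (u_sum - u_sum_h1) / (ki - floor(ki / 2))),
    observed_ids = observed_ids,
    trait = trait,
    config = cfg
  ), class = "st_fit")
}

#' Predicted genetic values from a single-trait fit
#'
#' Returns the posterior-mean genetic values for the requested lines; these
#' were augmented during sampling, so the call is deterministic given the
#' fit.
#'
#' @param fit an \code{st_fit}.
#' @param target_ids line ids (must have been in K at fitting time).
#' @return named numeric vector of predicted genetic values.
#' @export
predict_st <- function(fit, target_ids) {
  missing_ids <- setdiff(target_ids, names(fit$u_hat))
  if (length(missing_ids) > 0L)
    stop("unknown line ids: ", paste(missing_ids, collapse = ", "))
  fit$u_hat[target_ids]
}
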