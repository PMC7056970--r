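# Phenotypic analysis of plot-level multi-environment trial data: genotype
# BLUEs, variance components, Cullis heritability, correlations and PCA.

# Subset a plot table to one trait and an environment scope; scope is "ALL",
# a single environment id, or a character vector of environment ids.
scope_plots <- function(plots, trait, scope) {
  d <- plots[plots$trait == trait & !is.na(plots$value), , drop = FALSE]
  if (!identical(scope, "ALL")) d <- d[d$environment %in% scope, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no data for trait '%s' in scope", trait))
  d
}

scope_label <- function(scope) {
  if (identical(scope, "ALL")) "ALL" else paste(scope, collapse = "+")
}

# Build the design pieces shared by the BLUE and heritability fits.
# Multi-environment scope: random environment, block-in-environment and GEI;
# single environment: random block only (E and GEI terms dropped).
met_design <- function(d) {
  d$line_id <- factor(d$line_id)
  d$environment <- factor(d$environment)
  d$eb <- factor(paste(d$environment, d$block, sep = ":"))
  multi_env <- nlevels(d$environment) > 1L
  Zlist <- list()
  if (multi_env) {
    Zlist$env <- inc_matrix(d$environment)
    Zlist$block <- inc_matrix(d$eb)
    Zlist$gei <- inc_matrix(factor(paste(d$line_id, d$environment, sep = ":")))
  } else {
    if (nlevels(d$eb) > 1L) {
      Zlist$block <- inc_matrix(d$eb)
    } else if (max(table(d$line_id)) < 2L) {
      stop("single environment with one block and no replication: model unidentifiable")
    }
  }
  list(d = d, Zlist = Zlist, multi_env = multi_env)
}

varcomp_from_fit <- function(fit) {
  vc <- list(var_env = 0, var_block = 0, var_gei = 0, var_geno = NA_real_,
             var_resid = fit$var_resid,
             converged = fit$converged, n_iter = fit$n_iter,
             loglik = fit$loglik)
  for (nm in names(fit$var_comp)) {
    key <- switch(nm, env = "var_env", block = "var_block", gei = "var_gei",
                  geno = "var_geno", nm)
    vc[[key]] <- unname(fit$var_comp[[nm]])
  }
  structure(vc, class = "variance_components")
}

#' Genotype BLUEs from plot-level data
#'
#' Fits the multi-environment trial model
#' \code{y = mu + E + B(E) + G + GE + e} with genotype fixed and environment,
#' block-in-environment and GEI random, variance components estimated by
#' EM-REML on Henderson's mixed-model equations. For a single-environment
#' scope the E and GEI terms are dropped. BLUEs are reported on the trait
#' scale as intercept + genotype effect (first genotype as reference), with
#' standard errors from the inverse coefficient matrix.
#'
#' @param plots a \code{plot_table} (columns line_id, environment, block,
#'   trait, value).
#' @param trait trait name.
#' @param scope \code{"ALL"}, one environment id, or a character vector of
#'   environment ids to combine.
#' @param tol,max_iter EM-REML convergence controls (relative log-likelihood
#'   change and iteration cap). Non-convergence is flagged, not an error.
#' @return A list with \code{blues} (data.frame line_id, trait, scope, blue,
#'   se) and \code{var_comp} (a \code{variance_components}).
#' @export
fit_blues <- function(plots, trait, scope = "ALL", tol = 1e-8, max_iter = 500L) {
  d0 <- scope_plots(plots, trait, scope)
  if (length(unique(d0$line_id)) < 2L) stop("need >= 2 lines with data in scope")
  des <- met_design(d0)
  d <- des$d
  G <- inc_matrix(d$line_id)
  # intercept + treatment contrasts: column 1 absorbs the first genotype
  X <- cbind(`(Intercept)` = 1, G[, -1L, drop = FALSE])
  fit <- emreml(d$value, X, des$Zlist, tol = tol, max_iter = max_iter)
  lines <- levels(d$line_id)
  eff <- c(0, fit$beta[-1L])
  blue <- fit$beta[1L] + eff
  # se of (intercept + effect_l): contrast row is e1 + e_l
  Cb <- fit$Cinv[seq_len(fit$p), seq_len(fit$p), drop = FALSE] * fit$var_resid
  se <- sqrt(pmax(vapply(seq_along(lines), function(l) {
    if (l == 1L) Cb[1L, 1L]
    else Cb[1L, 1L] + Cb[l, l] + 2 * Cb[1L, l]
  }, numeric(1L)), 0))
  blues <- data.frame(line_id = lines, trait = trait,
                      scope = scope_label(scope),
                      blue = unname(blue), se = unname(se))
  class(blues) <- c("blue_table", "data.frame")
  list(blues = blues, var_comp = varcomp_from_fit(fit))
}

#' Cullis broad-sense heritability
#'
#' Refits the [fit_blues()] model with genotype random, extracts the mean
#' pairwise prediction-error variance of the genotype BLUPs from the inverse
#' coefficient matrix, and returns
#' \code{H2 = 1 - vbar_BLUP / (2 * sigma2_g)}, clamped to [0, 1]. An
#' estimated genotypic variance at (numerical) zero yields \code{H2 = 0} with
#' a degenerate flag.
#'
#' @inheritParams fit_blues
#' @return A list of class \code{heritability}: \code{H2}, \code{vbar_blup},
#'   \code{var_geno}, \code{degenerate}, plus the full variance components.
#' @export
fit_h2 <- function(plots, trait, scope = "ALL", tol = 1e-8, max_iter = 500L) {
  d0 <- scope_plots(plots, trait, scope)
  if (length(unique(d0$line_id)) < 2L) stop("need >= 2 lines with data in scope")
  des <- met_design(d0)
  d <- des$d
  Zlist <- c(list(geno = inc_matrix(d$line_id)), des$Zlist)
  X <- matrix(1, nrow(d), 1L, dimnames = list(NULL, "(Intercept)"))
  fit <- emreml(d$value, X, Zlist, tol = tol, max_iter = max_iter)
  s2g <- unname(fit$var_comp[["geno"]])
  # PEV of genotype BLUPs: sigma2_e times the genotype block of Cinv
  gix <- fit$zblk[[1L]]
  PEV <- fit$Cinv[gix, gix, drop = FALSE] * fit$var_resid
  ng <- length(gix)
  sd_ <- sum(diag(PEV))
  vbar <- (ng * sd_ - sum(PEV)) * 2 / (ng * (ng - 1))
  degenerate <- s2g < 1e-8
  H2 <- if (degenerate) 0 else min(max(1 - vbar / (2 * s2g), 0), 1)
  structure(list(H2 = H2, vbar_blup = vbar, var_geno = s2g,
                 degenerate = degenerate,
                 var_comp = varcomp_from_fit(fit)),
            class = "heritability")
}

# Wide line x variable matrix from a BLUE table. By default variables are
# traits at a fixed scope; with by = "environment" they are the scopes of a
# fixed trait (used for environment-by-environment correlations).
blues_wide <- function(blues, scope = NULL, trait = NULL) {
  if (!is.null(trait)) {
    d <- blues[blues$trait == trait, , drop = FALSE]
    var <- d$scope
  } else {
    d <- blues
    if (!is.null(scope)) d <- d[d$scope == scope, , drop = FALSE]
    var <- d$trait
  }
  if (nrow(d) == 0L) stop("no BLUE records selected")
  lines <- sort(unique(d$line_id))
  vars <- unique(var)
  M <- matrix(NA_real_, length(lines), length(vars),
              dimnames = list(lines, vars))
  M[cbind(match(d$line_id, lines), match(var, vars))] <- d$blue
  M
}

#' Pairwise Pearson correlations with p-values
#'
#' Pairwise-complete Pearson correlations between the columns of a line-by-
#' variable matrix of BLUEs, with two-sided p-values from the t distribution
#' on n - 2 degrees of freedom. Serves both trait-by-trait correlations (one
#' scope) and environment-by-environment correlations (one trait across
#' scopes). Pairs with fewer than 3 complete observations get NA.
#'
#' @param blues a \code{blue_table} or a numeric lines x variables matrix.
#' @param scope when \code{blues} is a table: scope label to correlate traits
#'   within.
#' @param trait when set, correlate environments (scopes) of this trait
#'   instead.
#' @return list with matrices \code{r}, \code{p} and \code{n} (pairs used).
#' @export
trait_correlations <- function(blues, scope = "ALL", trait = NULL) {
  M <- if (is.matrix(blues)) blues else blues_wide(blues, scope = scope, trait = trait)
  k <- ncol(M)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(M[, i], M[, j])
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < 3L) next
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      rij <- stats::cor(M[ok, i], M[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tstat <- rij * sqrt((nij - 2) / (1 - rij^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df = nij - 2)
      }
    }
  }
  list(r = r, p = p, n = nmat)
}

#' Principal component analysis of the trait correlation matrix
#'
#' Eigendecomposition of the correlation matrix of trait BLUEs (complete
#' cases only). Returns the proportion of variance explained per component,
#' trait loadings, and for each component the traits ranked by absolute
#' loading (used to build the PC-derived trait sets).
#'
#' @inheritParams trait_correlations
#' @return list of class \code{trait_pca}: \code{pve}, \code{loadings},
#'   \code{ranked} (list of trait vectors, one per PC), \code{eigenvalues}.
#' @export
trait_pca <- function(blues, scope = "ALL") {
  M <- if (is.matrix(blues)) blues else blues_wide(blues, scope = scope)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (ncol(M) < 2L || nrow(M) < 3L)
    stop("PCA needs >= 2 traits and >= 3 complete lines")
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) stop("constant trait column; correlation undefined")
  R <- stats::cor(M)
  ee <- eigen(R, symmetric = TRUE)
  pve <- ee$values / sum(ee$values)
  L <- ee$vectors
  dimnames(L) <- list(colnames(M), paste0("PC", seq_len(ncol(M))))
  ranked <- lapply(seq_len(ncol(L)), function(j) {
    names(sort(abs(L[, j]), decreasing = TRUE))
  })
  structure(list(pve = pve, loadings = L, ranked = ranked,
                 eigenvalues = ee$values),
            class = "trait_pca")
}
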