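# CV1/CV2 cross-validation of single- and multi-trait genomic prediction:
# partition generation, trait-set strategies, predictive ability, and
# prediction into un-phenotyped environments.

#' Cross-validation scheme description
#'
#' @param scheme \code{"CV1"} (test lines unphenotyped for every trait) or
#'   \code{"CV2"} (test lines keep their correlated-trait phenotypes and
#'   lose only the target trait).
#' @param train_fraction fraction of lines in the training set.
#' @param n_repeats number of random train/test splits.
#' @param seed seed from which every repeat's split is derived.
#' @return list of class \code{cv_scheme}.
#' @export
cv_scheme <- function(scheme = c("CV1", "CV2"), train_fraction = 0.6,
                      n_repeats = 100L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1L)
  structure(list(scheme = scheme, train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Random train/test partitions
#'
#' Generates \code{n_repeats} independent splits at the scheme's training
#' fraction (training size = \code{round(frac * n)}). Each repeat uses its
#' own RNG stream derived from the scheme seed, so the full partition list
#' is reproducible from the seed and any prefix of it is stable.
#'
#' @param line_ids character vector of line ids (>= 10).
#' @param scheme a [cv_scheme()].
#' @return list of length \code{n_repeats}; each element has \code{train}
#'   and \code{test} id vectors (disjoint, exhaustive).
#' @export
make_partitions <- function(line_ids, scheme) {
  n <- length(line_ids)
  if (n < 10L) stop("need >= 10 lines for cross-validation")
  n_train <- round(scheme$train_fraction * n)
  if (n_train < 2L || n - n_train < 2L)
    stop("train or test size < 2 at this train_fraction")
  lapply(seq_len(scheme$n_repeats), function(r) {
    set.seed(derive_seed(scheme$seed, r))
    tr <- sample(line_ids, n_train)
    list(train = tr, test = setdiff(line_ids, tr))
  })
}

#' Predictive ability
#'
#' Pearson correlation between predicted genetic values and observed BLUEs
#' on a test set. Returns NA (rather than erroring) when either vector has
#' zero variance; fewer than 3 pairs is an error.
#'
#' @param predicted,observed paired numeric vectors.
#' @return scalar correlation in [-1, 1] or NA.
#' @export
predictive_ability <- function(predicted, observed) {
  ok <- is.finite(predicted) & is.finite(observed)
  if (sum(ok) < 3L) stop("need >= 3 paired values")
  if (stats::sd(predicted[ok]) == 0 || stats::sd(observed[ok]) == 0)
    return(NA_real_)
  stats::cor(predicted[ok], observed[ok])
}

#' Build the standard trait-set strategies
#'
#' AGRO is the four agronomic traits; A+M adds the four malting traits; COR1
#' is the set positively correlated with grain protein content; COR2/COR3
#' are the four traits loading most heavily (in absolute value) on the first
#' and second principal components of the trait correlation matrix. The
#' target trait is appended to any set that lacks it.
#'
#' @param blues a \code{blue_table} with the eight default traits at
#'   \code{scope}.
#' @param target the trait to be predicted.
#' @param scope scope label for the PCA.
#' @return named list of \code{trait_set} lists (name, members, target).
#' @export
build_trait_sets <- function(blues, target, scope = "ALL") {
  have <- unique(blues$trait)
  absent <- setdiff(DEFAULT_TRAITS, have)
  if (length(absent) > 0L)
    stop("missing default traits: ", paste(absent, collapse = ", "))
  agro <- c("YLD", "TGW", "GM2", "PLM")
  malt <- c("BGL", "EXT", "SNI", "GPC")
  pca <- trait_pca(blues, scope = scope)
  sets <- list(
    AGRO = agro,
    `A+M` = c(agro, malt),
    COR1 = c("BGL", "PLM", "SNI", "GPC"),
    COR2 = pca$ranked[[1L]][1:4],
    COR3 = pca$ranked[[2L]][1:4]
  )
  lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    members <- unique(c(sets[[nm]], target))
    structure(list(name = nm, members = members, target = target),
              class = "trait_set")
  })
}

#' User-defined trait set
#'
#' @param members ordered trait names (target appended if absent).
#' @param target the trait to be predicted.
#' @param name label for reporting.
#' @return a \code{trait_set}.
#' @export
trait_set <- function(members, target, name = "custom") {
  structure(list(name = name, members = unique(c(members, target)),
                 target = target), class = "trait_set")
}

cv_summary <- function(r_pa) {
  ok <- r_pa[is.finite(r_pa)]
  c(mean = mean(ok), sd = stats::sd(ok),
    stats::quantile(ok, c(0, 0.25, 0.5, 0.75, 1),
                    names = FALSE) |>
      stats::setNames(c("min", "q1", "median", "q3", "max")),
    n_missing = sum(!is.finite(r_pa)))
}

# One repeat of CV for a trait-set strategy. CV1 masks every trait of the
# test lines; CV2 masks only the target, keeping the test lines' correlated
# traits in the training likelihood.
cv_repeat <- function(Y, blues, K, strategy, scheme_name, cfg, part, scope) {
  lines <- rownames(K)
  target <- strategy$target
  members <- strategy$members
  y_true <- Y[, target]
  if (length(members) == 1L) {
    fit <- fit_st(blues, target, K, cfg, observed_ids = part$train,
                  scope = scope)
    pred <- predict_st(fit, part$test)
  } else {
    mask <- matrix(TRUE, length(lines), length(members),
                   dimnames = list(lines, members))
    if (scheme_name == "CV1") {
      mask[part$test, ] <- FALSE
    } else {
      mask[part$test, target] <- FALSE
    }
    fit <- fit_mt(blues, members, K, cfg, mask = mask, scope = scope)
    pred <- fit$U_hat[part$test, target]
  }
  predictive_ability(pred, y_true[part$test])
}

#' Run a cross-validation comparison
#'
#' For each repeat, splits the lines, builds the scheme's missing pattern
#' (CV1: test lines lose all traits; CV2: test lines lose only the target),
#' fits the multi-trait model (or the single-trait model when the strategy
#' has one member, in which case CV1 and CV2 coincide by construction), and
#' scores the Pearson correlation between predicted genetic values and the
#' held-out BLUEs of the target trait. Pass a shared \code{partitions} list
#' to pair the repeats across strategies and schemes.
#'
#' @param blues a \code{blue_table}.
#' @param K a \code{kinship_matrix} covering all lines to cross-validate.
#' @param strategy a \code{trait_set}.
#' @param scheme a [cv_scheme()].
#' @param cfg a [gibbs_config()]; each repeat derives its own chain seed.
#' @param scope scope label of the BLUEs used.
#' @param partitions optional precomputed [make_partitions()] output.
#' @return list of class \code{cv_result}: \code{r_pa} per repeat,
#'   \code{summary}, \code{partitions}, and the run descriptors.
#' @export
run_cv <- function(blues, K, strategy, scheme, cfg = gibbs_config(),
                   scope = "ALL", partitions = NULL) {
  lines <- rownames(K)
  Y <- blues_matrix(blues, strategy$members, lines, scope)
  if (anyNA(Y[, strategy$target]))
    stop("target trait must have a BLUE for every line of K")
  if (is.null(partitions)) partitions <- make_partitions(lines, scheme)
  r_pa <- vapply(seq_along(partitions), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(cfg$seed, 1000L + r)
    cv_repeat(Y, blues, K, strategy, scheme$scheme, cfg_r,
              partitions[[r]], scope)
  }, numeric(1L))
  structure(list(
    r_pa = r_pa,
    summary = cv_summary(r_pa),
    target = strategy$target,
    strategy = strategy$name,
    scheme = scheme$scheme,
    scope = scope_label(scope),
    partitions = partitions
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s / %s / %s, %d repeats, mean r_PA = %.3f (sd %.3f)\n",
              x$target, x$strategy, x$scheme, length(x$r_pa),
              x$summary[["mean"]], x$summary[["sd"]]))
  invisible(x)
}

#' Genomic prediction into an un-phenotyped environment
#'
#' Stacks each (trait, source environment) BLUE as a separate variable of
#' the multi-trait model, together with the target trait in the target
#' environment, then cross-validates: MT-CV1 masks every variable of the
#' test lines, MT-CV2 masks only the target variable (so test lines keep
#' their source-environment records). Scoring is against the held-out
#' target-environment BLUEs. Leave-one-location-out or leave-one-year-out
#' groupings are expressed through \code{source_scopes}.
#'
#' @param blues_by_env a \code{blue_table} whose \code{scope} column holds
#'   environment labels.
#' @param K a \code{kinship_matrix}.
#' @param target_env environment to predict into (must not be a source).
#' @param target_trait trait scored in the target environment.
#' @param scheme a [cv_scheme()].
#' @param cfg a [gibbs_config()].
#' @param source_scopes environments supplying phenotypes; default all
#'   scopes in the table except \code{target_env}.
#' @param source_traits traits taken from the source environments; default
#'   all traits present.
#' @return a \code{cv_result}.
#' @export
env_prediction <- function(blues_by_env, K, target_env, target_trait,
                           scheme, cfg = gibbs_config(),
                           source_scopes = NULL, source_traits = NULL) {
  scopes_all <- unique(blues_by_env$scope)
  if (is.null(source_scopes)) source_scopes <- setdiff(scopes_all, target_env)
  if (target_env %in% source_scopes) stop("target environment cannot be a source")
  if (length(source_scopes) < 1L) stop("need >= 1 source environment")
  if (is.null(source_traits)) source_traits <- unique(blues_by_env$trait)
  lines <- rownames(K)

  # stack (trait @ environment) variables into one synthetic blue table
  stack_one <- function(tr, sc) {
    d <- blues_by_env[blues_by_env$trait == tr & blues_by_env$scope == sc, ,
                      drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    data.frame(line_id = d$line_id, trait = paste(tr, sc, sep = "@"),
               scope = "STACK", blue = d$blue, se = d$se)
  }
  pieces <- c(
    lapply(source_traits, function(tr)
      do.call(rbind, lapply(source_scopes, function(sc) stack_one(tr, sc)))),
    list(stack_one(target_trait, target_env))
  )
  stacked <- do.call(rbind, pieces)
  target_var <- paste(target_trait, target_env, sep = "@")
  if (!target_var %in% stacked$trait)
    stop("target (trait, environment) has no BLUEs to score against")
  members <- c(setdiff(unique(stacked$trait), target_var), target_var)
  strategy <- structure(list(name = "ENV", members = members,
                             target = target_var), class = "trait_set")
  run_cv(stacked, K, strategy, scheme, cfg, scope = "STACK")
}
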