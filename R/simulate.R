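#' Default trait names: four agronomic and four malting-quality traits
#'
#' Grain yield (YLD), grains per square meter (GM2), thousand grain weight
#' (TGW), grain plumpness (PLM), beta-glucan content (BGL), malt extract
#' (EXT), soluble nitrogen (SNI) and grain protein content (GPC).
#' @export
DEFAULT_TRAITS <- c("YLD", "GM2", "TGW", "PLM", "BGL", "EXT", "SNI", "GPC")

# A plausible genetic correlation structure for the eight default traits:
# yield trades off against protein, protein clusters with the malting traits,
# and the yield-component block (YLD, GM2, TGW, GPC) dominates the first
# principal component while the malting block (BGL, PLM, SNI, EXT) dominates
# the second.
default_trait_corr <- function() {
  tr <- DEFAULT_TRAITS
  R <- diag(8)
  dimnames(R) <- list(tr, tr)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("YLD", "GM2", 0.7); set_r("YLD", "TGW", 0.0); set_r("YLD", "PLM", 0.4)
  set_r("YLD", "BGL", -0.1); set_r("YLD", "EXT", 0.1); set_r("YLD", "SNI", -0.2)
  set_r("YLD", "GPC", -0.5)
  set_r("GM2", "TGW", -0.4); set_r("GM2", "PLM", 0.2); set_r("GM2", "BGL", -0.2)
  set_r("GM2", "EXT", 0.1); set_r("GM2", "SNI", -0.3); set_r("GM2", "GPC", -0.5)
  set_r("TGW", "PLM", 0.3); set_r("TGW", "BGL", 0.2); set_r("TGW", "EXT", -0.1)
  set_r("TGW", "SNI", 0.2); set_r("TGW", "GPC", 0.4)
  set_r("PLM", "BGL", 0.2); set_r("PLM", "EXT", -0.1); set_r("PLM", "SNI", 0.2)
  set_r("PLM", "GPC", 0.3)
  set_r("BGL", "EXT", -0.4); set_r("BGL", "SNI", 0.5); set_r("BGL", "GPC", 0.5)
  set_r("EXT", "SNI", -0.3); set_r("EXT", "GPC", -0.5)
  set_r("SNI", "GPC", 0.6)
  make_pd_corr(R)
}

#' Configuration for the doubled-haploid study simulator
#'
#' Defaults mirror a connected four-family barley DH panel: 145 lines from
#' four crosses of five parents (33/39/45/28 lines), roughly 6.5k mapped
#' biallelic SNPs on 7 chromosomes, 8 correlated traits, and 9 environments
#' with strong genotype-by-environment interaction for the agronomic traits
#' and weak GEI for the quality traits. Every default can be overridden.
#'
#' @param n_families number of biparental families.
#' @param lines_per_family integer vector, DH lines per family.
#' @param n_parents number of parents in the (connected) crossing scheme.
#' @param chrom_lengths_cM genetic length of each chromosome in centimorgans.
#' @param n_markers total number of markers, allocated to chromosomes in
#'   proportion to genetic length and spaced uniformly.
#' @param n_traits number of traits.
#' @param trait_names trait labels; defaults to [DEFAULT_TRAITS] when
#'   \code{n_traits == 8}.
#' @param Sigma_g trait-by-trait genetic covariance (the simulation truth).
#' @param Sigma_e trait-by-trait within-plot residual covariance.
#' @param trait_means per-trait grand means.
#' @param n_envs,n_blocks environments and blocks nested in environment.
#' @param var_env,var_block,var_gei per-trait variance components for the
#'   environment main effect, block-in-environment, and GEI deviations
#'   (scalars are recycled across traits).
#' @param replicate_fraction fraction of lines used as replicated checks that
#'   appear in every block; the remaining lines appear once per environment.
#' @param missing_geno_rate proportion of genotype calls set to missing.
#' @param seed integer seed controlling all stages of the generator.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 4L,
                       lines_per_family = c(33L, 39L, 45L, 28L),
                       n_parents = 5L,
                       chrom_lengths_cM = rep(150, 7),
                       n_markers = 6482L,
                       n_traits = 8L,
                       trait_names = NULL,
                       Sigma_g = NULL,
                       Sigma_e = NULL,
                       trait_means = NULL,
                       n_envs = 9L,
                       n_blocks = 2L,
                       var_env = 3,
                       var_block = 0.5,
                       var_gei = c(2, 2, 2, 2, 0.5, 0.5, 0.5, 0.5),
                       replicate_fraction = 8 / 145,
                       missing_geno_rate = 0.005,
                       seed = 1L) {
  if (is.null(trait_names)) {
    trait_names <- if (n_traits == 8L) DEFAULT_TRAITS else paste0("T", seq_len(n_traits))
  }
  if (is.null(Sigma_g)) {
    Sigma_g <- if (n_traits == 8L) default_trait_corr() else diag(n_traits)
    dimnames(Sigma_g) <- list(trait_names, trait_names)
  }
  if (is.null(Sigma_e)) {
    Sigma_e <- diag(n_traits)
    dimnames(Sigma_e) <- list(trait_names, trait_names)
  }
  if (is.null(trait_means)) trait_means <- stats::setNames(rep(0, n_traits), trait_names)
  recycle <- function(x) stats::setNames(rep_len(x, n_traits), trait_names)
  cfg <- structure(list(
    n_families = as.integer(n_families),
    lines_per_family = as.integer(lines_per_family),
    n_parents = as.integer(n_parents),
    chrom_lengths_cM = as.numeric(chrom_lengths_cM),
    n_markers = as.integer(n_markers),
    n_traits = as.integer(n_traits),
    trait_names = trait_names,
    Sigma_g = Sigma_g,
    Sigma_e = Sigma_e,
    trait_means = recycle(trait_means),
    n_envs = as.integer(n_envs),
    n_blocks = as.integer(n_blocks),
    var_env = recycle(var_env),
    var_block = recycle(var_block),
    var_gei = recycle(var_gei),
    replicate_fraction = replicate_fraction,
    missing_geno_rate = missing_geno_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(lines_per_family) != n_families)
      stop("lines_per_family must have n_families entries")
    if (n_families < 1L || n_parents < 2L || n_markers < 1L || n_traits < 1L ||
        n_envs < 1L || n_blocks < 1L)
      stop("counts must be >= 1 (and n_parents >= 2)")
    if (any(chrom_lengths_cM <= 0)) stop("chromosome lengths must be > 0")
    if (!is_symmetric_psd(Sigma_g)) stop("Sigma_g must be symmetric PSD")
    if (!is_symmetric_psd(Sigma_e)) stop("Sigma_e must be symmetric PSD")
    if (any(c(var_env, var_block, var_gei) < 0)) stop("variances must be >= 0")
    if (replicate_fraction < 0 || replicate_fraction > 1)
      stop("replicate_fraction must be in [0, 1]")
    if (missing_geno_rate < 0 || missing_geno_rate >= 1)
      stop("missing_geno_rate must be in [0, 1)")
  })
  invisible(cfg)
}

# Allocate n_markers across chromosomes proportional to genetic length,
# remainders to the longest chromosomes; markers spaced uniformly.
marker_map <- function(chrom_lengths_cM, n_markers) {
  nc <- length(chrom_lengths_cM)
  prop <- chrom_lengths_cM / sum(chrom_lengths_cM)
  base <- floor(prop * n_markers)
  rem <- n_markers - sum(base)
  if (rem > 0) {
    ord <- order(prop * n_markers - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  if (any(base == 0L))
    stop("marker allocation leaves a chromosome with zero markers; ",
         "increase n_markers or drop the chromosome")
  map <- do.call(rbind, lapply(seq_len(nc), function(cc) {
    m <- base[cc]
    data.frame(
      chrom = cc,
      pos_cM = chrom_lengths_cM[cc] * (seq_len(m) - 0.5) / m
    )
  }))
  map$marker <- sprintf("M%d_%04d", map$chrom, ave(map$chrom, map$chrom, FUN = seq_along))
  rownames(map) <- map$marker
  map[, c("marker", "chrom", "pos_cM")]
}

# One meiosis under the Haldane map function (no interference): the parental
# origin along a chromosome is a Markov chain whose switch probability between
# adjacent markers is the recombination fraction r = (1 - exp(-2d/100))/2.
# Returns an n_gametes x n_markers 0/1 matrix of parental origins.
sim_gamete_origins <- function(n_gametes, pos_cM) {
  m <- length(pos_cM)
  start <- matrix(stats::rbinom(n_gametes, 1L, 0.5), n_gametes, 1L)
  if (m == 1L) return(start)
  d <- diff(pos_cM)
  r <- 0.5 * (1 - exp(-2 * d / 100))
  switches <- matrix(
    stats::rbinom(n_gametes * (m - 1L), 1L, rep(r, each = n_gametes)),
    n_gametes, m - 1L
  )
  row_cumsum_mod2(cbind(start, switches))
}

#' Simulate connected biparental doubled-haploid families
#'
#' Parents are independent fully homozygous haplotypes with allele frequency
#' 0.5 at every marker. Families come from a chain crossing scheme (cross i
#' mates parent i with parent i+1) so the population is connected. Each DH
#' line is a single gamete of the family's F1, formed by recombination under
#' the Haldane map function and then chromosome doubling, so every genotype is
#' homozygous: codes are -1/+1 (by allele identity) with missing calls
#' inserted at \code{missing_geno_rate}.
#'
#' @param config a [sim_config()].
#' @return A \code{marker_matrix}: list with \code{geno} (lines x markers,
#'   codes -1/+1/NA), \code{map} (marker, chrom, pos_cM), \code{family}
#'   (named factor of family labels) and \code{qc_state = "raw"}.
#' @export
simulate_dh_families <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  map <- marker_map(config$chrom_lengths_cM, config$n_markers)
  m <- nrow(map)
  n <- sum(config$lines_per_family)

  # parent haplotypes: rows = parents, entries 0/1
  parents <- matrix(stats::rbinom(config$n_parents * m, 1L, 0.5),
                    config$n_parents, m)
  crosses <- cbind(
    ((seq_len(config$n_families) - 1L) %% config$n_parents) + 1L,
    (seq_len(config$n_families) %% config$n_parents) + 1L
  )

  geno <- matrix(NA_integer_, n, m)
  fam <- character(n)
  row0 <- 0L
  chrom_idx <- split(seq_len(m), map$chrom)
  for (f in seq_len(config$n_families)) {
    nf <- config$lines_per_family[f]
    hapA <- parents[crosses[f, 1L], ]
    hapB <- parents[crosses[f, 2L], ]
    alleles <- matrix(NA_integer_, nf, m)
    for (idx in chrom_idx) {
      orig <- sim_gamete_origins(nf, map$pos_cM[idx])
      alleles[, idx] <- ifelse(orig == 0L,
                               rep(hapA[idx], each = nf),
                               rep(hapB[idx], each = nf))
    }
    geno[row0 + seq_len(nf), ] <- 2L * alleles - 1L
    fam[row0 + seq_len(nf)] <- sprintf("FAM%d", f)
    row0 <- row0 + nf
  }
  line_ids <- sprintf("%s_L%03d", fam, unlist(lapply(config$lines_per_family, seq_len)))
  dimnames(geno) <- list(line_ids, map$marker)
  if (config$missing_geno_rate > 0) {
    nmiss <- stats::rbinom(1L, n * m, config$missing_geno_rate)
    if (nmiss > 0) geno[sample(n * m, nmiss)] <- NA_integer_
  }
  structure(list(
    geno = geno,
    map = map,
    family = stats::setNames(factor(fam), line_ids),
    qc_state = "raw"
  ), class = "marker_matrix")
}

#' Simulate true breeding values through marker effects
#'
#' Marker effects are drawn per marker as multivariate normal across traits
#' with covariance \code{Sigma_g / m_eff}, where \code{m_eff} is the sum of
#' per-marker genotype variances \code{4 p (1 - p)} on the inbred -1/+1 scale,
#' so the breeding-value covariance across lines targets \code{Sigma_g}.
#' Breeding values are the centered (mean-imputed) genotype matrix times the
#' marker effects, giving an additive, infinitesimal-like architecture whose
#' covariance structure a marker-estimated kinship can recover.
#'
#' @param markers a \code{marker_matrix}.
#' @param config a [sim_config()] (only \code{Sigma_g}, trait names and seed
#'   are used).
#' @return A \code{true_genetics} list: \code{breeding_values} (lines x
#'   traits), \code{marker_effects} (markers x traits) and
#'   \code{realized_Sigma_g}.
#' @export
simulate_true_values <- function(markers, config) {
  if (!is_symmetric_psd(config$Sigma_g)) stop("Sigma_g must be symmetric PSD")
  set.seed(derive_seed(config$seed, 2L))
  X <- markers$geno
  cm <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    miss <- which(is.na(X), arr.ind = TRUE)
    X[miss] <- cm[miss[, 2L]]
  }
  p <- (cm + 1) / 2
  varm <- 4 * p * (1 - p)
  if (all(varm == 0)) stop("all markers are monomorphic")
  m_eff <- sum(varm)
  t <- config$n_traits
  B <- matrix(stats::rnorm(ncol(X) * t), ncol(X), t) %*%
    sym_sqrt(config$Sigma_g / m_eff)
  colnames(B) <- config$trait_names
  W <- sweep(X, 2L, cm)
  u <- W %*% B
  dimnames(u) <- list(rownames(X), config$trait_names)
  structure(list(
    breeding_values = u,
    marker_effects = B,
    realized_Sigma_g = stats::cov(u)
  ), class = "true_genetics")
}

#' Simulate plot-level phenotypes in an augmented partially replicated design
#'
#' Each environment carries \code{n_blocks} blocks; a check set of
#' \code{round(replicate_fraction * n)} lines appears in every block and the
#' remaining lines appear once per environment (assigned round-robin to
#' blocks). Each plot value is
#' \code{mu_trait + E_env + B_block(env) + u_line + GE_line,env + e}, with the
#' environment, block and GEI deviations independent normal at the configured
#' per-trait variances and the plot residual multivariate normal across traits
#' with covariance \code{Sigma_e}.
#'
#' @param truth a \code{true_genetics} object.
#' @param config a [sim_config()].
#' @return A tidy \code{data.frame} (class \code{plot_table}) with columns
#'   line_id, family, environment, block, trait, value.
#' @export
simulate_plot_phenotypes <- function(truth, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 3L))
  u <- truth$breeding_values
  lines <- rownames(u)
  n <- length(lines)
  tn <- config$trait_names
  t <- config$n_traits
  k <- round(config$replicate_fraction * n)
  checks <- lines[seq_len(k)]
  tests <- setdiff(lines, checks)

  envs <- sprintf("ENV%02d", seq_len(config$n_envs))
  E <- matrix(stats::rnorm(config$n_envs * t, sd = rep(sqrt(config$var_env), each = config$n_envs)),
              config$n_envs, t, dimnames = list(envs, tn))
  GE <- array(stats::rnorm(n * config$n_envs * t,
                           sd = rep(sqrt(config$var_gei), each = n * config$n_envs)),
              dim = c(n, config$n_envs, t), dimnames = list(lines, envs, tn))
  Se_sqrt <- sym_sqrt(config$Sigma_e)

  rows <- vector("list", config$n_envs)
  for (i in seq_len(config$n_envs)) {
    blocks <- sprintf("B%d", seq_len(config$n_blocks))
    Bef <- matrix(stats::rnorm(config$n_blocks * t,
                               sd = rep(sqrt(config$var_block), each = config$n_blocks)),
                  config$n_blocks, t, dimnames = list(blocks, tn))
    # round-robin assignment of unreplicated lines to blocks
    test_block <- blocks[((seq_along(tests) - 1L) %% config$n_blocks) + 1L]
    plot_line <- c(rep(checks, times = config$n_blocks), tests)
    plot_block <- c(rep(blocks, each = length(checks)), test_block)
    np <- length(plot_line)
    resid <- matrix(stats::rnorm(np * t), np, t) %*% Se_sqrt
    Y <- matrix(rep(config$trait_means, each = np), np, t) +
      matrix(rep(E[i, ], each = np), np, t) +
      Bef[plot_block, , drop = FALSE] +
      u[plot_line, , drop = FALSE] +
      GE[plot_line, i, ] +
      resid
    rows[[i]] <- data.frame(
      line_id = rep(plot_line, times = t),
      environment = envs[i],
      block = rep(plot_block, times = t),
      trait = rep(tn, each = np),
      value = as.vector(Y)
    )
  }
  out <- do.call(rbind, rows)
  fam <- attr(truth, "family")
  out$family <- as.character(NA)
  out <- out[, c("line_id", "family", "environment", "block", "trait", "value")]
  rownames(out) <- NULL
  class(out) <- c("plot_table", "data.frame")
  out
}

#' Simulate a complete study data set in one call
#'
#' Runs [simulate_dh_families()], [simulate_true_values()] and
#' [simulate_plot_phenotypes()] with one configuration, returning all three
#' pieces (genotypes with map, simulation truth, plot phenotypes).
#'
#' @param config a [sim_config()].
#' @return A list with elements \code{markers}, \code{truth}, \code{plots}.
#' @export
simulate_study <- function(config = sim_config()) {
  markers <- simulate_dh_families(config)
  truth <- simulate_true_values(markers, config)
  plots <- simulate_plot_phenotypes(truth, config)
  plots$family <- as.character(markers$family[plots$line_id])
  list(markers = markers, truth = truth, plots = plots)
}
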