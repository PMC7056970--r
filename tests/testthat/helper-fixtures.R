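# Small in-code fixtures shared across test files.

# A compact two-trait DH study: genotypes, kinship and line-level BLUEs
# built as breeding value + independent noise at chosen heritabilities.
# u_mode "markers" routes breeding values through marker effects (end-to-end
# realism, but family LD makes the realized covariance drift from Sigma_g);
# u_mode "direct" draws u from Sigma (x) K exactly, the controlled setting
# for parameter-recovery oracles.
quick_study <- function(seed, n_fam = 2L, fam_size = 50L, n_markers = 800L,
                        rho_g = 0.7, h2 = c(0.5, 0.5),
                        traits = c("TGT", "HLP"), u_mode = "markers") {
  cfg <- sim_config(
    n_families = n_fam, lines_per_family = rep(fam_size, n_fam),
    n_parents = n_fam + 1L, n_markers = n_markers,
    chrom_lengths_cM = rep(120, 5),
    n_traits = 2L, trait_names = traits,
    Sigma_g = matrix(c(1, rho_g, rho_g, 1), 2L),
    Sigma_e = diag(2L), seed = seed, missing_geno_rate = 0
  )
  mk <- simulate_dh_families(cfg)
  tv <- simulate_true_values(mk, cfg)
  K <- additive_relationship(qc_filter(mk))
  n <- nrow(K)
  set.seed(derive_seed(seed, 5L))
  if (u_mode == "direct") {
    # exact-model draw: vec(u) ~ MVN(0, Sigma (x) K), scaled so the average
    # line variance per trait is Sigma_g's diagonal (~1)
    Sig <- cfg$Sigma_g / mean(diag(K))
    L <- t(chol(kronecker(Sig, unclass(K)) + diag(1e-8, 2L * n)))
    u <- matrix(as.vector(L %*% stats::rnorm(2L * n)), n, 2L,
                dimnames = list(rownames(K), traits))
  } else {
    u <- tv$breeding_values
  }
  Y <- sapply(1:2, function(j) u[, j] + stats::rnorm(n, sd = sqrt(1 / h2[j] - 1)))
  blues <- data.frame(
    line_id = rep(rownames(u), 2L), trait = rep(traits, each = n),
    scope = "ALL", blue = as.vector(Y), se = NA_real_
  )
  list(cfg = cfg, markers = mk, truth = tv, K = K, blues = blues, u = u)
}

# Line-level BLUE table straight from a matrix of values.
blues_from_matrix <- function(Y, scope = "ALL") {
  data.frame(
    line_id = rep(rownames(Y), ncol(Y)),
    trait = rep(colnames(Y), each = nrow(Y)),
    scope = scope, blue = as.vector(Y), se = NA_real_
  )
}

# Tiny marker_matrix from an explicit genotype matrix (all mapped to chrom 1
# unless a chrom vector is given).
toy_markers <- function(geno, chrom = NULL, qc_state = "raw") {
  if (is.null(chrom)) chrom <- rep(1L, ncol(geno))
  map <- data.frame(marker = colnames(geno), chrom = chrom,
                    pos_cM = seq_len(ncol(geno)) * 10)
  rownames(map) <- map$marker
  structure(list(geno = geno, map = map, family = NULL, qc_state = qc_state),
            class = "marker_matrix")
}

# Shorter chains for unit tests; posterior means at this scale are stable
# enough for the tolerances used.
test_gibbs <- function(seed = 1L, n_iter = 1200L, burn_in = 400L) {
  gibbs_config(n_iter = n_iter, burn_in = burn_in, seed = seed)
}

# 20 lines x 5 markers QC toy: A fails call rate (0.90), B fails MAF
# (0.025), C is unmapped, D and E are clean.
make_toy_qc <- function() {
  A <- c(rep(NA_integer_, 2L), rep(c(-1L, 1L), 9L))
  # one heterozygote among 20 lines carries a single minor copy: MAF 1/40
  B <- c(0L, rep(1L, 19L))
  C <- rep(c(1L, -1L), 10L)
  D <- rep(c(-1L, 1L), 10L)
  E <- c(rep(-1L, 6L), rep(1L, 14L))
  geno <- cbind(A = A, B = B, C = C, D = D, E = E)
  rownames(geno) <- sprintf("L%02d", 1:20)
  toy_markers(geno, chrom = c(1L, 1L, NA, 2L, 2L))
}
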