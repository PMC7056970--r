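# A balanced complete two-environment design with known effects.
balanced_plots <- function(n_lines = 12L, n_envs = 2L, n_blocks = 2L,
                           u = NULL, sd_e = 0, seed = 1L) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  if (is.null(u)) u <- stats::setNames(stats::rnorm(n_lines), lines)
  d <- expand.grid(line_id = lines, environment = sprintf("E%d", seq_len(n_envs)),
                   block = sprintf("B%d", seq_len(n_blocks)),
                   stringsAsFactors = FALSE)
  d$trait <- "T"
  d$value <- u[d$line_id] + if (sd_e > 0) stats::rnorm(nrow(d), sd = sd_e) else 0
  d
}

test_that("noise-free balanced data reproduce line means exactly", {
  d <- balanced_plots(sd_e = 0)
  fb <- fit_blues(d, "T")
  means <- tapply(d$value, d$line_id, mean)
  expect_equal(fb$blues$blue, as.numeric(means[fb$blues$line_id]),
               tolerance = 1e-6)
  vc <- fb$var_comp
  expect_lt(vc$var_env + vc$var_block + vc$var_gei, 1e-4)
  expect_lt(vc$var_resid, 1e-4)
})

test_that("a two-line two-block toy gives the hand-solved BLUE difference", {
  d <- data.frame(line_id = c("L1", "L2", "L1", "L2"),
                  environment = "E1",
                  block = c("B1", "B1", "B2", "B2"),
                  trait = "T",
                  value = c(10, 12, 14, 16))
  fb <- fit_blues(d, "T", scope = "E1")
  b <- stats::setNames(fb$blues$blue, fb$blues$line_id)
  # block effects cancel in the contrast: L2 - L1 = 2 exactly
  expect_equal(unname(b["L2"] - b["L1"]), 2, tolerance = 1e-8)
})

test_that("the GEI-to-genotype variance ratio is recovered", {
  # agronomic-like setting: var_gei / var_geno = 2
  ratios <- vapply(1:8, function(r) {
    cfg <- sim_config(n_families = 2L, lines_per_family = c(50L, 50L),
                      n_parents = 3L, n_markers = 400L,
                      chrom_lengths_cM = rep(120, 5),
                      n_traits = 1L, trait_names = "T",
                      Sigma_g = matrix(1), Sigma_e = matrix(1),
                      n_envs = 4L, n_blocks = 2L,
                      var_env = 1, var_block = 0.2, var_gei = 2,
                      replicate_fraction = 0.25,
                      missing_geno_rate = 0, seed = 100L + r)
    s <- simulate_study(cfg)
    h <- fit_h2(s$plots, "T")
    h$var_comp$var_gei / h$var_comp$var_geno
  }, numeric(1L))
  expect_lt(abs(mean(ratios) - 2), 0.5)
})

test_that("EM-REML matches lme4 on variance components and BLUEs", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_families = 1L, lines_per_family = 40L, n_parents = 2L,
                    n_markers = 200L, chrom_lengths_cM = rep(120, 3),
                    n_traits = 1L, trait_names = "T",
                    Sigma_g = matrix(1), Sigma_e = matrix(0.8),
                    n_envs = 3L, n_blocks = 2L,
                    var_env = 1.5, var_block = 0.3, var_gei = 0.7,
                    missing_geno_rate = 0, seed = 33L)
  s <- simulate_study(cfg)
  fb <- fit_blues(s$plots, "T")
  d <- s$plots[s$plots$trait == "T", ]
  d$eb <- paste(d$environment, d$block)
  m <- lme4::lmer(
    value ~ 0 + line_id + (1 | environment) + (1 | eb) +
      (1 | line_id:environment),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(m))
  ref <- stats::setNames(vc$vcov, vc$grp)
  expect_equal(fb$var_comp$var_env, unname(ref["environment"]), tolerance = 0.02)
  expect_equal(fb$var_comp$var_gei, unname(ref["line_id:environment"]),
               tolerance = 0.02)
  expect_equal(fb$var_comp$var_resid, unname(ref["Residual"]), tolerance = 0.02)
  fe <- lme4::fixef(m)
  expect_gt(stats::cor(fb$blues$blue,
                       fe[paste0("line_id", fb$blues$line_id)]), 0.999999)
})

test_that("the EM-REML log-likelihood is non-decreasing", {
  cfg <- sim_config(n_families = 1L, lines_per_family = 30L, n_parents = 2L,
                    n_markers = 100L, chrom_lengths_cM = rep(100, 2),
                    n_traits = 1L, trait_names = "T", Sigma_g = matrix(1),
                    n_envs = 2L, seed = 3L)
  s <- simulate_study(cfg)
  fb <- fit_blues(s$plots, "T")
  expect_true(all(diff(fb$var_comp$loglik) > -1e-6))
  expect_true(all(unlist(fb$var_comp[c("var_env", "var_block", "var_gei",
                                       "var_resid")]) >= 0))
})

test_that("BLUE contrasts are invariant to a constant shift of one block", {
  d <- balanced_plots(sd_e = 0.5, seed = 7L)
  fb0 <- fit_blues(d, "T")
  d2 <- d
  shift <- d2$environment == "E1" & d2$block == "B1"
  d2$value[shift] <- d2$value[shift] + 100
  fb1 <- fit_blues(d2, "T")
  diff0 <- fb0$blues$blue - fb0$blues$blue[1L]
  diff1 <- fb1$blues$blue - fb1$blues$blue[1L]
  expect_equal(diff0, diff1, tolerance = 1e-6)
})

test_that("heritability is one without noise and matches the balanced formula", {
  d <- balanced_plots(sd_e = 0)
  h <- fit_h2(d, "T")
  expect_equal(h$H2, 1, tolerance = 1e-3)

  # with noise: Cullis H2 close to the balanced plug-in formula
  cfg <- sim_config(n_families = 2L, lines_per_family = c(40L, 40L),
                    n_parents = 3L, n_markers = 300L,
                    chrom_lengths_cM = rep(120, 4),
                    n_traits = 1L, trait_names = "T",
                    Sigma_g = matrix(1), Sigma_e = matrix(1),
                    n_envs = 3L, n_blocks = 2L,
                    var_env = 1, var_block = 0.2, var_gei = 0.5,
                    replicate_fraction = 1,   # fully replicated -> balanced
                    missing_geno_rate = 0, seed = 21L)
  s <- simulate_study(cfg)
  h2 <- fit_h2(s$plots, "T")
  vc <- h2$var_comp
  e <- 3; r <- 2
  plug_in <- vc$var_geno /
    (vc$var_geno + vc$var_gei / e + vc$var_resid / (e * r))
  expect_lt(abs(h2$H2 - plug_in), 0.05)
})

test_that("degenerate genotypic variance yields H2 = 0 with a flag", {
  # pure-noise phenotypes: genotype variance collapses to the floor
  d <- balanced_plots(u = stats::setNames(rep(0, 12L), sprintf("L%02d", 1:12)),
                      sd_e = 1, seed = 9L)
  h <- fit_h2(d, "T")
  if (h$degenerate) expect_equal(h$H2, 0)
  expect_lt(h$H2, 0.35)
})

test_that("correlations match hand-computed values and handle edge cases", {
  M <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(3, 2, 4, 9))
  rownames(M) <- paste0("L", 1:4)
  ct <- trait_correlations(M)
  expect_equal(ct$r["a", "a"], 1)
  expect_equal(ct$p["a", "a"], 0)
  expect_equal(ct$r["a", "b"], 1)           # exact collinearity
  expect_equal(ct$p["a", "b"], 0)
  M2 <- cbind(x = c(1, 2, 3), y = c(3, 2, 4))
  rownames(M2) <- paste0("L", 1:3)
  expect_equal(trait_correlations(M2)$r["x", "y"], 0.5)
  # fewer than 3 complete pairs -> NA
  M3 <- cbind(x = c(1, 2, NA, NA), y = c(NA, 4, 5, 6))
  rownames(M3) <- paste0("L", 1:4)
  expect_true(is.na(trait_correlations(M3)$r["x", "y"]))
})

test_that("PCA recovers degenerate and independent structures", {
  # two perfectly correlated traits: PC1 explains everything
  M <- cbind(a = c(1, 2, 3, 5), b = 2 * c(1, 2, 3, 5))
  rownames(M) <- paste0("L", 1:4)
  p <- trait_pca(M)
  expect_equal(p$pve[1L], 1, tolerance = 1e-12)
  # exactly orthogonal zero-mean columns: identity correlation, equal PVE
  H <- stats::contr.helmert(5L)
  colnames(H) <- paste0("t", 1:4)
  rownames(H) <- paste0("L", 1:5)
  p2 <- trait_pca(H)
  expect_equal(p2$pve, rep(0.25, 4L), tolerance = 1e-12)
  # constant column errors
  Mc <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  rownames(Mc) <- paste0("L", 1:3)
  expect_error(trait_pca(Mc), "constant")
})

test_that("PCA separates two independent blocks of correlated traits", {
  set.seed(11)
  n <- 200L
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  blk1 <- sapply(1:4, function(i) z1 + stats::rnorm(n, sd = 0.4))
  blk2 <- sapply(1:4, function(i) z2 + stats::rnorm(n, sd = 0.6))
  M <- cbind(blk1, blk2)
  colnames(M) <- c(paste0("A", 1:4), paste0("B", 1:4))
  rownames(M) <- sprintf("L%03d", 1:n)
  p <- trait_pca(M)
  expect_setequal(p$ranked[[1L]][1:4], paste0("A", 1:4))
  expect_setequal(p$ranked[[2L]][1:4], paste0("B", 1:4))
})

test_that("identifiability and scope rules are enforced", {
  d <- data.frame(line_id = c("L1", "L2", "L3"), environment = "E1",
                  block = "B1", trait = "T", value = c(1, 2, 3))
  expect_error(fit_blues(d, "T", scope = "E1"), "unidentifiable")
  expect_error(fit_blues(d, "X"), "no data")
})
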