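test_that("partitions honor the 60/40 split and are seed-reproducible", {
  ids <- sprintf("L%03d", 1:145)
  sch <- cv_scheme("CV1", n_repeats = 5L, seed = 42L)
  parts <- make_partitions(ids, sch)
  expect_length(parts, 5L)
  for (p in parts) {
    expect_length(p$train, 87L)   # round(0.6 * 145)
    expect_length(p$test, 58L)
    expect_length(intersect(p$train, p$test), 0L)
    expect_setequal(c(p$train, p$test), ids)
  }
  parts2 <- make_partitions(ids, sch)
  expect_identical(parts, parts2)
  parts3 <- make_partitions(ids, cv_scheme("CV1", n_repeats = 5L, seed = 43L))
  expect_false(identical(parts[[1L]]$train, parts3[[1L]]$train))
})

test_that("degenerate split sizes are rejected", {
  expect_error(make_partitions(sprintf("L%d", 1:8), cv_scheme()), ">= 10")
  expect_error(
    make_partitions(sprintf("L%d", 1:12),
                    cv_scheme(train_fraction = 0.95, n_repeats = 2L)),
    "train or test")
})

test_that("predictive ability matches hand-computed correlations", {
  expect_equal(predictive_ability(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(predictive_ability(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(predictive_ability(c(1, 2, 3), c(3, 2, 4)), 0.5)
  expect_true(is.na(predictive_ability(c(1, 1, 1), c(1, 2, 3))))
  expect_error(predictive_ability(c(1, 2), c(1, 2)), ">= 3")
  # affine rescaling of either side leaves r_PA unchanged
  set.seed(1)
  a <- stats::rnorm(20); b <- a + stats::rnorm(20)
  expect_equal(predictive_ability(a, b), predictive_ability(2 * a + 7, b))
})

test_that("standard trait-set strategies are assembled correctly", {
  # line x trait BLUEs whose correlation structure mirrors the default
  # generator: yield-component block on PC1, malting block on PC2
  set.seed(2)
  n <- 400L
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  Y <- cbind(
    YLD = z1 + stats::rnorm(n, sd = 0.45),
    GM2 = z1 + stats::rnorm(n, sd = 0.45),
    TGW = z1 + stats::rnorm(n, sd = 0.45),
    GPC = -z1 + stats::rnorm(n, sd = 0.45),
    BGL = z2 + stats::rnorm(n, sd = 0.65),
    EXT = -z2 + stats::rnorm(n, sd = 0.65),
    SNI = z2 + stats::rnorm(n, sd = 0.65),
    PLM = z2 + stats::rnorm(n, sd = 0.65)
  )
  rownames(Y) <- sprintf("L%03d", seq_len(n))
  blues <- blues_from_matrix(Y)
  sets <- build_trait_sets(blues, target = "GPC")
  expect_named(sets, c("AGRO", "A+M", "COR1", "COR2", "COR3"))
  expect_setequal(sets$AGRO$members, c("YLD", "TGW", "GM2", "PLM", "GPC"))
  expect_setequal(sets$`A+M`$members, DEFAULT_TRAITS)
  expect_setequal(sets$COR1$members, c("BGL", "PLM", "SNI", "GPC"))
  # PC1 carries the yield-component block, PC2 the malting block
  expect_setequal(sets$COR2$members, c("YLD", "GM2", "TGW", "GPC"))
  expect_setequal(sets$COR3$members, c("BGL", "EXT", "SNI", "PLM", "GPC"))
  # the target is appended where absent and every set contains it
  for (s in sets) expect_true("GPC" %in% s$members)
  expect_error(build_trait_sets(blues[blues$trait != "EXT", ], "GPC"),
               "EXT")
})

test_that("CV1 and CV2 coincide for a single-trait strategy", {
  s <- quick_study(seed = 81L, n_fam = 2L, fam_size = 40L, n_markers = 500L)
  st <- trait_set("TGT", "TGT", "ST")
  parts <- make_partitions(rownames(s$K), cv_scheme("CV1", n_repeats = 3L,
                                                    seed = 5L))
  cfg <- test_gibbs(seed = 6L, n_iter = 900L, burn_in = 300L)
  r1 <- run_cv(s$blues, s$K, st, cv_scheme("CV1", n_repeats = 3L, seed = 5L),
               cfg, partitions = parts)
  r2 <- run_cv(s$blues, s$K, st, cv_scheme("CV2", n_repeats = 3L, seed = 5L),
               cfg, partitions = parts)
  expect_identical(r1$r_pa, r2$r_pa)
})

test_that("a heritability-zero trait has predictive ability near zero", {
  s <- quick_study(seed = 82L, n_fam = 2L, fam_size = 50L, n_markers = 500L)
  b <- s$blues
  set.seed(3)
  b$blue[b$trait == "TGT"] <- stats::rnorm(100)   # pure noise target
  r <- run_cv(b, s$K, trait_set("TGT", "TGT", "ST"),
              cv_scheme("CV1", n_repeats = 4L, seed = 7L),
              test_gibbs(seed = 8L, n_iter = 900L, burn_in = 300L))
  # |mean r_PA| within ~2/sqrt(n_test) of zero
  expect_lt(abs(r$summary[["mean"]]), 2 / sqrt(40))
})

test_that("cross-validation results are reproducible end to end", {
  s <- quick_study(seed = 83L, n_fam = 2L, fam_size = 40L, n_markers = 400L)
  mt <- trait_set(c("TGT", "HLP"), "TGT", "MT")
  sch <- cv_scheme("CV2", n_repeats = 2L, seed = 11L)
  cfg <- test_gibbs(seed = 12L, n_iter = 700L, burn_in = 250L)
  r1 <- run_cv(s$blues, s$K, mt, sch, cfg)
  r2 <- run_cv(s$blues, s$K, mt, sch, cfg)
  expect_identical(r1$r_pa, r2$r_pa)
  expect_true(all(r1$r_pa >= -1 & r1$r_pa <= 1))
})

test_that("environment prediction honors GEI structure and the CV2 edge", {
  # two-environment stack built from breeding values plus env-specific GEI
  build_env_blues <- function(seed, var_gei) {
    s <- quick_study(seed = seed, n_fam = 3L, fam_size = 50L,
                     n_markers = 800L, u_mode = "direct")
    n <- nrow(s$K)
    set.seed(derive_seed(seed, 9L))
    pieces <- lapply(c("E1", "E2"), function(env) {
      ge <- stats::rnorm(n, sd = sqrt(var_gei))
      data.frame(line_id = rownames(s$K), trait = "TGT", scope = env,
                 blue = s$u[, "TGT"] + ge + stats::rnorm(n, sd = sqrt(0.4)),
                 se = NA_real_)
    })
    list(K = s$K, blues = do.call(rbind, pieces))
  }
  sch1 <- cv_scheme("CV1", n_repeats = 3L, seed = 21L)
  sch2 <- cv_scheme("CV2", n_repeats = 3L, seed = 21L)
  cfg <- test_gibbs(seed = 22L, n_iter = 900L, burn_in = 300L)

  lo <- build_env_blues(84L, var_gei = 0.1)   # quality-like, weak GEI
  hi <- build_env_blues(84L, var_gei = 2)     # agronomic-like, strong GEI
  r_lo <- env_prediction(lo$blues, lo$K, "E2", "TGT", sch2, cfg)
  r_hi <- env_prediction(hi$blues, hi$K, "E2", "TGT", sch2, cfg)
  expect_gt(r_lo$summary[["mean"]], r_hi$summary[["mean"]])

  r_lo_cv1 <- env_prediction(lo$blues, lo$K, "E2", "TGT", sch1, cfg)
  expect_gte(r_lo$summary[["mean"]], r_lo_cv1$summary[["mean"]] - 0.02)
  expect_error(env_prediction(lo$blues, lo$K, "E2", "TGT", sch1, cfg,
                              source_scopes = c("E1", "E2")),
               "cannot be a source")
})

test_that("without GEI, cross-environment prediction matches within-environment", {
  s <- quick_study(seed = 85L, n_fam = 3L, fam_size = 50L, n_markers = 800L,
                   h2 = c(0.6, 0.6), u_mode = "direct")
  n <- nrow(s$K)
  set.seed(31)
  mk_env <- function(env) data.frame(
    line_id = rownames(s$K), trait = "TGT", scope = env,
    blue = s$u[, "TGT"] + stats::rnorm(n, sd = sqrt(1 / 0.6 - 1)),
    se = NA_real_
  )
  benv <- rbind(mk_env("E1"), mk_env("E2"))
  sch <- cv_scheme("CV1", n_repeats = 4L, seed = 41L)
  cfg <- test_gibbs(seed = 42L, n_iter = 900L, burn_in = 300L)
  r_env <- env_prediction(benv, s$K, "E2", "TGT", sch, cfg)
  b2 <- benv[benv$scope == "E2", ]
  b2$scope <- "ALL"
  r_within <- run_cv(b2, s$K, trait_set("TGT", "TGT", "ST"), sch, cfg)
  expect_lt(abs(r_env$summary[["mean"]] - r_within$summary[["mean"]]), 0.1)
})
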