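test_that("saturated unweighted test equals the classical regression F test", {
  set.seed(61)
  for (i in 1:5) {
    n <- sample(80:150, 1)
    m <- sample(4:8, 1)
    reg <- make_unrelated(n, m, seed = 610 + i, common = TRUE)
    x1 <- rnorm(n)
    y <- rnorm(n)
    dat <- phenotype_data(y, covariates = cbind(x1))
    # order = m: polynomial basis, invertible at any m distinct points,
    # so the functional design spans the full genotype space
    res <- flm_test(reg, dat, weights = weight_spec("none"),
                    effect_spec = basis_spec("bspline", m, order = m))
    orc <- ols_ftest(y, dat$X, reg$G)
    expect_equal(res$F_stat, orc$F, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
    expect_equal(res$df1, orc$df1)
    expect_equal(res$df2, orc$df2)
  }
})

test_that("genotype smoothing with identical bases equals beta-smooth only", {
  tested <- 0L
  i <- 0L
  while (tested < 10L) {
    i <- i + 1L
    reg <- make_unrelated(120, 28 + (i %% 12), seed = 620 + i)
    set.seed(640 + i)
    dat <- phenotype_data(rnorm(120))
    spec <- if (i %% 2) basis_spec("bspline", 15) else basis_spec("fourier", 15)
    full <- tryCatch(
      flm_test(reg, dat, genotype_spec = spec, effect_spec = spec),
      error = function(e) NULL)    # Phi'Phi singular: precondition unmet
    if (is.null(full)) next
    tested <- tested + 1L
    bonly <- flm_test(reg, dat, effect_spec = spec)
    expect_equal(full$F_stat, bonly$F_stat, tolerance = 1e-8)
    expect_equal(full$p_value, bonly$p_value, tolerance = 1e-8)
  }
})

test_that("(1,1) beta weights reproduce the unweighted model exactly", {
  reg <- make_unrelated(200, 35, seed = 63)
  set.seed(63)
  dat <- phenotype_data(rnorm(200))
  r_unw <- flm_test(reg, dat, weights = weight_spec("none"))
  r_11 <- flm_test(reg, dat, weights = weight_spec("beta", 1, 1))
  expect_identical(r_11$F_stat, r_unw$F_stat)
  expect_identical(r_11$p_value, r_unw$p_value)
})

test_that("the reported P value is consistent with (F, df1, df2)", {
  reg <- make_unrelated(150, 30, seed = 64)
  set.seed(64)
  dat <- phenotype_data(rnorm(150))
  res <- flm_test(reg, dat)
  expect_equal(res$p_value,
               pf(res$F_stat, res$df1, res$df2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("rank detection drops duplicated and null directions", {
  set.seed(65)
  A <- matrix(rnorm(200), 50, 4)
  dup <- cbind(A, A[, 2])
  rg <- rank_guard(dup)
  expect_equal(rg$rank, 4L)
  expect_equal(ncol(rg$design), 4L)
  expect_error(rank_guard(matrix(0, 10, 3)), "rank 0")
  expect_equal(rank_guard(A)$rank, qr(A, LAPACK = TRUE)$rank)
})

test_that("mixed-model F test agrees with dense GLS computation", {
  fam <- make_family_sample(30, 30, seed = 66)
  n <- nrow(fam$R)
  set.seed(66)
  y <- simulate_trait(fam$region, h2 = 0.29, R = fam$R)
  dat <- phenotype_data(y)
  fit <- fit_null(dat, fam$R)
  res <- flm_test(fam$region, dat, fit)
  # oracle: whiten by a dense symmetric inverse square root and use lm
  Omega <- fit$sigma_g2 * fam$R + fit$sigma_e2 * diag(n)
  e <- eigen(Omega, symmetric = TRUE)
  Oih <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  pos <- scale_positions(fam$region$positions)
  W <- bspline_basis(pos$scaled, 15)
  Z <- fam$region$G %*% (beta_weights(fam$region$mafs, 1, 25) * W)
  orc <- ols_ftest(Oih %*% y, Oih %*% dat$X, Oih %*% Z)
  expect_equal(res$F_stat, orc$F, tolerance = 1e-8)
  expect_equal(res$p_value, orc$p, tolerance = 1e-8)
})

test_that("misaligned or overparametrized inputs raise errors", {
  reg <- make_unrelated(30, 25, seed = 67)
  set.seed(67)
  expect_error(flm_test(reg, phenotype_data(rnorm(25))), "sample size")
  dat <- phenotype_data(rnorm(30), ids = paste0("X", 1:30))
  expect_error(flm_test(reg, dat), "ids")
  # n too small for K_beta: no residual degrees of freedom
  reg_small <- make_unrelated(10, 30, seed = 68)
  set.seed(68)
  expect_error(flm_test(reg_small, phenotype_data(rnorm(10))),
               "overparametrized")
})

test_that("result objects print, summarise and expose coefficients", {
  reg <- make_unrelated(100, 30, seed = 69)
  set.seed(69)
  dat <- phenotype_data(rnorm(100))
  res <- flm_test(reg, dat)
  expect_output(print(res), "F = ")
  expect_output(summary(res), "coefficient")
  expect_length(coef(res), 15L)
  tb <- results_table(list(res, res))
  expect_equal(nrow(tb), 2L)
  expect_equal(tb$P, rep(res$p_value, 2))
})
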