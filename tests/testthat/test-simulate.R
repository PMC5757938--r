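test_that("generators are reproducible bit-exactly from their seed", {
  r1 <- simulate_population_genotypes(100, 20, seed = 71)
  r2 <- simulate_population_genotypes(100, 20, seed = 71)
  expect_identical(r1$G, r2$G)
  expect_identical(r1$positions, r2$positions)
  f1 <- simulate_families(20, 15, seed = 72)
  f2 <- simulate_families(20, 15, seed = 72)
  expect_identical(f1$region$G, f2$region$G)
  expect_identical(f1$R, f2$R)
})

test_that("sample MAF tracks the population MAF at binomial precision", {
  fixed <- maf_sampler(lo = 0.3, hi = 0.3)    # degenerate: MAF = 0.3
  reg <- simulate_population_genotypes(1000, 10, fixed, seed = 73)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_true(all(abs(reg$mafs - 0.3) < 4 * se))
})

test_that("regions satisfy the rare-variant content requirement", {
  reg <- simulate_population_genotypes(700, 40, min_rare = 10, seed = 74)
  expect_gte(sum(reg$mafs <= 0.03), 10)
  expect_equal(ncol(reg$G), 40L)              # nothing monomorphic survived
  expect_true(all(reg$mafs > 0 & reg$mafs <= 0.5))
})

test_that("pedigree relationship matrix matches kinship theory", {
  ped <- nuclear_pedigree(2, 3)
  R <- pedigree_relmatrix(ped)
  expect_equal(unname(diag(R)), rep(1, 10))
  expect_equal(R["F1_1", "F1_2"], 0)          # founders unrelated
  expect_equal(R["F1_1", "F1_3"], 0.5)        # parent-offspring
  expect_equal(R["F1_3", "F1_4"], 0.5)        # full sibs
  expect_equal(max(abs(R[ped$fid == "F1", ped$fid == "F2"])), 0)
  expect_equal(R, t(R))
})

test_that("gene-dropping conserves allele frequency in expectation", {
  ped <- nuclear_pedigree(60, 4)
  off <- is.na(ped$father) == FALSE
  set.seed(75)
  freqs <- replicate(200, {
    G <- wflm:::gene_drop(ped, 0.3)
    mean(G[off, 1]) / 2
  })
  expect_lt(abs(mean(freqs) - 0.3), 3 * sd(freqs) / sqrt(200))
})

test_that("effect magnitudes follow the printed effect-size laws", {
  # region with two variants at sample MAF exactly 0.01 and 0.5
  G <- cbind(c(rep(1, 2), rep(0, 98)), rep(1, 100))
  reg <- region_genotypes(G, c(10, 20))
  expect_equal(reg$mafs, c(0.01, 0.5))
  sc1 <- sim_scenario(prop_causal = 1, prop_same_direction = 1,
                      causal_pool = "all", effect_model = "log_maf", s = 2)
  eff1 <- draw_effects(reg, sc1, seed = 76)
  expect_equal(eff1$beta[1], log(2), tolerance = 1e-12)       # |log10(.01)|/2 = 1
  expect_equal(eff1$beta[2], log(2) * abs(log10(0.5)) / 2, tolerance = 1e-12)
  expect_true(all(eff1$beta > 0))             # 100% same direction
  sc2 <- sim_scenario(prop_causal = 1, causal_pool = "all",
                      effect_model = "variance_standardized", s = 0.1)
  eff2 <- draw_effects(reg, sc2, seed = 77)
  expect_equal(eff2$beta[2], 0.1 / sqrt(2 * 0.25), tolerance = 1e-12)
  # rare-only pool with no rare variants errors
  common <- region_genotypes(matrix(rbinom(400, 2, 0.4), 100), c(1, 2, 3, 4))
  sc3 <- sim_scenario(causal_pool = "rare_only")
  expect_error(draw_effects(common, sc3), "empty")
})

test_that("simulated traits have the model covariance structure", {
  reg <- simulate_population_genotypes(2000, 5, seed = 78)
  y <- simulate_trait(reg, seed = 79)         # beta = 0, R = I
  expect_lt(abs(var(y) - 1), 4 / sqrt(2000))
  # sib covariance h2 * 0.5 under the family null
  fam <- simulate_families(100, 5, seed = 80)
  L <- wflm:::trait_chol(0.29, fam$R)
  set.seed(81)
  sib1 <- which(!is.na(fam$pedigree$father))[c(TRUE, FALSE, FALSE, FALSE)]
  prods <- replicate(500, {
    y <- drop(L %*% rnorm(nrow(fam$R)))
    mean(y[sib1] * y[sib1 + 1])
  })
  expect_lt(abs(mean(prods) - 0.29 * 0.5), 3 * sd(prods) / sqrt(500))
  # determinism
  expect_identical(simulate_trait(reg, seed = 82), simulate_trait(reg, seed = 82))
})

test_that("type-I experiment hits the trivial significance bounds", {
  res <- run_type1("population", n = 100, n_replicates = 60, n_regions = 4,
                   m_range = c(26, 30), alphas = c(0, 0.5, 1), seed = 83)
  expect_equal(res$rates$rate[res$rates$alpha == 0], 0)
  expect_equal(res$rates$rate[res$rates$alpha == 1], 1)
  expect_length(res$p_values, 60L)
})

test_that("bulk experiment engine reproduces flm_test replicate by replicate", {
  t1 <- run_type1("population", n = 150, n_replicates = 8, n_regions = 4,
                  m_range = c(26, 34), seed = 84, keep = TRUE)
  t2 <- run_type1("family", n = 120, n_replicates = 6, n_regions = 3,
                  m_range = c(26, 34), seed = 85, keep = TRUE)
  for (tt in list(t1, t2)) {
    R <- tt$panel$R
    for (b in seq_along(tt$p_values)) {
      r <- tt$region_index[b]
      col <- sum(tt$region_index[seq_len(b)] == r)
      dat <- phenotype_data(tt$traits[[r]][, col])
      ref <- flm_test(tt$panel$regions[[r]], dat, fit_null(dat, R))
      expect_equal(tt$p_values[b], ref$p_value, tolerance = 1e-6)
    }
  }
})

test_that("null P values are uniform for both sample types", {
  tp <- run_type1("population", n = 400, n_replicates = 10000, seed = 86,
                  n_regions = 20)
  expect_gt(suppressWarnings(ks.test(tp$p_values, "punif"))$p.value, 0.01)
  tf <- run_type1("family", n = 300, n_replicates = 2000, seed = 87,
                  n_regions = 10)
  expect_gt(suppressWarnings(ks.test(tf$p_values, "punif"))$p.value, 0.01)
  # Fourier basis and the milder weighting are calibrated too
  tp2 <- run_type1("population", n = 400, n_replicates = 4000, seed = 88,
                   n_regions = 20, effect_spec = basis_spec("fourier", 25),
                   weights = weight_spec("beta", 0.5, 0.5))
  expect_gt(suppressWarnings(ks.test(tp2$p_values, "punif"))$p.value, 0.01)
})

test_that("power runs are seed-reproducible and respect common random numbers", {
  sc <- sim_scenario(prop_causal = 0.2, s = 3, n_replicates = 30)
  ws <- list(w = weight_spec("beta", 1, 25), u = weight_spec("none"))
  p1 <- run_power(sc, "population", n = 150, n_regions = 4,
                  m_range = c(26, 34), weights = ws, seed = 89)
  p2 <- run_power(sc, "population", n = 150, n_regions = 4,
                  m_range = c(26, 34), weights = ws, seed = 89)
  expect_identical(p1$p_values, p2$p_values)
  # single-spec call gives the same replicates as the list call
  p3 <- run_power(sc, "population", n = 150, n_regions = 4,
                  m_range = c(26, 34), weights = weight_spec("beta", 1, 25),
                  seed = 89)
  expect_equal(p3$p_values[, 1], p1$p_values[, 1])
  # a permissive threshold is always crossed
  expect_equal(colMeans(p1$p_values < 1.01), c(w = 1, u = 1))
})
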