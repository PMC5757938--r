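# Small fixtures built in code; all randomness under explicit seeds.

make_unrelated <- function(n, m, seed, common = FALSE) {
  set.seed(seed)
  sampler <- if (common) maf_sampler(2, 2) else maf_sampler()
  simulate_population_genotypes(n, m, sampler, min_rare = 0)
}

make_family_sample <- function(n_families, m, seed, n_offspring = 4L) {
  simulate_families(n_families, m, n_offspring = n_offspring, seed = seed)
}

# Textbook nested-model F test (independent of the package's whitened-QR
# path): residual sums of squares from lm fits.
ols_ftest <- function(y, X0, G) {
  f0 <- stats::lm(y ~ X0 - 1)
  f1 <- stats::lm(y ~ X0 + G - 1)
  a <- stats::anova(f0, f1)
  list(F = a$F[2L], p = a$`Pr(>F)`[2L], df1 = a$Df[2L], df2 = a$Res.Df[2L])
}
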