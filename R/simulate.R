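# Synthetic data emulating exome-like gene regions: a rare-skewed MAF
# spectrum, >= 25-30 polymorphic variants per region with >= 10 rare
# (MAF <= 0.03), unrelated or nuclear-family samples, and quantitative traits
# y ~ N(G beta, h2 R + (1 - h2) I).

#' Minor-allele frequency sampler specification
#'
#' Population MAFs are drawn from a beta distribution truncated to
#' `[lo, hi]`. The default `Beta(0.2, 2)` is strongly skewed toward rare
#' alleles, mimicking an exome site-frequency spectrum; the lower bound
#' defaults to `1/(2n)` (the smallest frequency observable in a sample of
#' `n` diploids) at generation time.
#'
#' @param a,b beta shape parameters.
#' @param lo,hi truncation bounds; `lo = NULL` means `1/(2n)`.
#' @return A list of class `"maf_sampler"`.
#' @export
maf_sampler <- function(a = 0.2, b = 2, lo = NULL, hi = 0.5) {
  stopifnot(a > 0, b > 0, hi <= 0.5)
  structure(list(a = a, b = b, lo = lo, hi = hi), class = "maf_sampler")
}

sample_mafs <- function(m, n, sampler) {
  lo <- sampler$lo %||% (1 / (2 * n))
  plo <- stats::pbeta(lo, sampler$a, sampler$b)
  phi <- stats::pbeta(sampler$hi, sampler$a, sampler$b)
  stats::qbeta(stats::runif(m, plo, phi), sampler$a, sampler$b)
}

#' Simulate genotypes for one region in an unrelated sample
#'
#' Population MAFs are drawn from `sampler`, dosages are independent
#' `Binomial(2, MAF)` across variants (no linkage disequilibrium), and
#' positions are distinct and uniform over a span of `span` base pairs.
#' Monomorphic columns are redrawn (new MAF and new genotypes); if
#' `min_rare > 0` the whole region is redrawn until at least that many
#' variants have sample MAF <= `rare_threshold`, mirroring the selection of
#' exome regions with a guaranteed rare-variant content.
#'
#' @param n number of individuals.
#' @param m number of variants.
#' @param sampler a [maf_sampler()].
#' @param min_rare minimum number of rare variants required.
#' @param rare_threshold MAF cutoff defining "rare".
#' @param span region length in base pairs.
#' @param region_id optional label.
#' @param seed optional seed (the generator also composes with an external
#'   `set.seed()` when `seed = NULL`).
#' @return A [region_genotypes()] object.
#' @export
simulate_population_genotypes <- function(n, m, sampler = maf_sampler(),
                                          min_rare = 0, rare_threshold = 0.03,
                                          span = 10000L, region_id = NULL,
                                          seed = NULL) {
  stopifnot(n >= 1, m >= 1)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(200L)) {
    mafs <- sample_mafs(m, n, sampler)
    G <- matrix(stats::rbinom(n * m, 2L, rep(mafs, each = n)), n, m)
    G <- redraw_monomorphic(G, function(k, cols) {
      mf <- sample_mafs(k, n, sampler)
      matrix(stats::rbinom(n * k, 2L, rep(mf, each = n)), n, k)
    })
    p <- colMeans(G) / 2
    p <- pmin(p, 1 - p)
    if (sum(p <= rare_threshold) >= min_rare) {
      pos <- sort(sample.int(span, m))
      return(region_genotypes(G, pos, ids = paste0("S", seq_len(n)),
                              region_id = region_id))
    }
  }
  stop("could not generate a region with >= ", min_rare,
       " rare variants in 200 attempts; relax min_rare or increase m")
}

# Replace monomorphic columns using `gen(k)` until all are polymorphic.
redraw_monomorphic <- function(G, gen) {
  for (it in seq_len(1000L)) {
    cs <- colSums(G)
    mono <- cs == 0L | cs == 2L * nrow(G)
    if (!any(mono)) return(G)
    G[, mono] <- gen(sum(mono), which(mono))
  }
  stop("monomorphic columns persisted after 1000 redraws")
}

#' Nuclear-family pedigree
#'
#' Builds a pedigree of `n_families` independent nuclear families, each with
#' two unrelated founders and `n_offspring` full-sib offspring.
#'
#' @param n_families number of families.
#' @param n_offspring offspring per family.
#' @return A data.frame with columns `fid`, `id`, `father`, `mother`
#'   (`NA` for founders), parents listed before offspring.
#' @export
nuclear_pedigree <- function(n_families, n_offspring = 4L) {
  stopifnot(n_families >= 1, n_offspring >= 1)
  do.call(rbind, lapply(seq_len(n_families), function(f) {
    fa <- sprintf("F%d_1", f); mo <- sprintf("F%d_2", f)
    kids <- sprintf("F%d_%d", f, 2L + seq_len(n_offspring))
    data.frame(fid = sprintf("F%d", f),
               id = c(fa, mo, kids),
               father = c(NA, NA, rep(fa, n_offspring)),
               mother = c(NA, NA, rep(mo, n_offspring)),
               stringsAsFactors = FALSE)
  }))
}

#' Expected additive relationship matrix from a pedigree
#'
#' Computes the numerator relationship matrix (2 x kinship; diagonal 1 for
#' outbred individuals) by the tabular method. Parents must appear before
#' their offspring.
#'
#' @param ped pedigree data.frame as from [nuclear_pedigree()].
#' @return `n x n` matrix with the pedigree `id`s as dimnames.
#' @export
pedigree_relmatrix <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  if (any(!is.na(fa) & fa >= seq_len(n)) || any(!is.na(mo) & mo >= seq_len(n)))
    stop("parents must be listed before their offspring")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    j <- seq_len(i - 1L)
    af <- if (!is.na(fa[i])) A[j, fa[i]] else numeric(length(j))
    am <- if (!is.na(mo[i])) A[j, mo[i]] else numeric(length(j))
    A[j, i] <- A[i, j] <- 0.5 * (af + am)
    A[i, i] <- 1 + if (!is.na(fa[i]) && !is.na(mo[i]))
      0.5 * A[fa[i], mo[i]] else 0
  }
  A
}

# Mendelian gene-dropping of independent biallelic sites through a pedigree.
# Founder haplotype alleles are Bernoulli(MAF); each offspring inherits one
# uniformly chosen allele from each parent, independently per site.
gene_drop <- function(ped, mafs) {
  n <- nrow(ped); m <- length(mafs)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      H1[i, ] <- stats::rbinom(m, 1L, mafs)
      H2[i, ] <- stats::rbinom(m, 1L, mafs)
    } else {
      pick <- stats::runif(m) < 0.5
      H1[i, ] <- ifelse(pick, H1[fa[i], ], H2[fa[i], ])
      pick <- stats::runif(m) < 0.5
      H2[i, ] <- ifelse(pick, H1[mo[i], ], H2[mo[i], ])
    }
  }
  H1 + H2
}

#' Simulate genotypes and relationship matrix for a family sample
#'
#' Draws founder alleles per variant from a rare-skewed MAF spectrum and
#' propagates them through a nuclear-family pedigree by Mendelian
#' gene-dropping. The relationship matrix is the expected additive
#' relationship from the pedigree (block-diagonal by family).
#'
#' @inheritParams simulate_population_genotypes
#' @param n_families number of nuclear families.
#' @param n_offspring offspring per family.
#' @return A list with components `region` (a [region_genotypes()]),
#'   `R` (relationship matrix) and `pedigree`.
#' @export
simulate_families <- function(n_families, m, n_offspring = 4L,
                              sampler = maf_sampler(), min_rare = 0,
                              rare_threshold = 0.03, span = 10000L,
                              region_id = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- nuclear_pedigree(n_families, n_offspring)
  R <- pedigree_relmatrix(ped)
  n <- nrow(ped)
  region <- gene_drop_region(ped, n, m, sampler, min_rare, rare_threshold,
                             span, region_id)
  list(region = region, R = R, pedigree = ped)
}

gene_drop_region <- function(ped, n, m, sampler, min_rare, rare_threshold,
                             span, region_id) {
  for (try in seq_len(200L)) {
    mafs <- sample_mafs(m, n, sampler)
    G <- gene_drop(ped, mafs)
    G <- redraw_monomorphic(G, function(k, cols)
      gene_drop(ped, sample_mafs(k, n, sampler)))
    p <- colMeans(G) / 2
    p <- pmin(p, 1 - p)
    if (sum(p <= rare_threshold) >= min_rare) {
      pos <- sort(sample.int(span, m))
      return(region_genotypes(G, pos, ids = ped$id, region_id = region_id))
    }
  }
  stop("could not generate a family region with >= ", min_rare,
       " rare variants in 200 attempts")
}

#' Simulation scenario for power experiments
#'
#' Bundles the axes of the power experiments: the proportion of causal
#' variants within the causal pool, the proportion of effects sharing one
#' direction, whether causal variants are drawn from rare variants only
#' (MAF <= 0.03) or from all variants, the effect-size law, its scale `s`,
#' the heritability of the polygenic background, and the replicate count.
#'
#' Effect laws: `"log_maf"` sets \eqn{|\beta_j| = \log(s)\,|\log_{10}
#' MAF_j|/2} (larger effects for rarer variants, but still a smaller variance
#' share); `"variance_standardized"` sets \eqn{|\beta_j| =
#' s/\sqrt{2\,MAF_j(1-MAF_j)}} (equal variance explained per causal variant).
#'
#' @param prop_causal proportion of the pool selected as causal, in (0, 1].
#' @param prop_same_direction proportion of causal effects with positive sign.
#' @param causal_pool `"rare_only"` or `"all"`.
#' @param effect_model `"log_maf"` or `"variance_standardized"`.
#' @param s effect scale, > 0 (typically 2, 3, 5, 7 for `"log_maf"`;
#'   0.01-0.1 for `"variance_standardized"`).
#' @param h2 heritability of the polygenic background, in [0, 1).
#' @param n_replicates number of simulation replicates.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(prop_causal = 0.1, prop_same_direction = 1,
                         causal_pool = c("rare_only", "all"),
                         effect_model = c("log_maf", "variance_standardized"),
                         s = 3, h2 = 0.29, n_replicates = 2000L) {
  causal_pool <- match.arg(causal_pool)
  effect_model <- match.arg(effect_model)
  stopifnot(prop_causal > 0, prop_causal <= 1,
            prop_same_direction >= 0, prop_same_direction <= 1,
            s > 0, h2 >= 0, h2 < 1, n_replicates >= 1)
  structure(list(prop_causal = prop_causal,
                 prop_same_direction = prop_same_direction,
                 causal_pool = causal_pool, effect_model = effect_model,
                 s = s, h2 = h2, n_replicates = as.integer(n_replicates)),
            class = "sim_scenario")
}

effect_magnitude <- function(mafs, effect_model, s) {
  switch(effect_model,
         log_maf = log(s) * abs(log10(mafs)) / 2,
         variance_standardized = s / sqrt(2 * mafs * (1 - mafs)))
}

#' Draw causal-variant effects for a region
#'
#' Selects a simple random sample of the causal pool (rare variants only, or
#' all variants), assigns magnitudes by the scenario's effect law, and signs
#' with the scenario's direction concordance (the positive count is rounded
#' to the nearest integer and assigned to a random subset).
#'
#' @param region a [region_genotypes()] object.
#' @param scenario a [sim_scenario()].
#' @param rare_threshold MAF cutoff defining the rare pool.
#' @param seed optional seed.
#' @return A list of class `"effect_vector"`: `beta` (length m, zero for
#'   non-causal variants) and `causal` (indices).
#' @export
draw_effects <- function(region, scenario, rare_threshold = 0.03,
                         seed = NULL) {
  stopifnot(inherits(region, "region_genotypes"),
            inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(region$G)
  pool <- if (scenario$causal_pool == "rare_only")
    which(region$mafs <= rare_threshold) else seq_len(m)
  if (length(pool) == 0L)
    stop("causal pool is empty (no variants with MAF <= ", rare_threshold, ")")
  n_causal <- max(1L, round(scenario$prop_causal * length(pool)))
  causal <- if (length(pool) == 1L) pool else sample(pool, n_causal)
  mag <- effect_magnitude(region$mafs[causal], scenario$effect_model,
                          scenario$s)
  n_pos <- round(scenario$prop_same_direction * n_causal)
  sgn <- rep(-1, n_causal)
  sgn[sample.int(n_causal, n_pos)] <- 1
  beta <- numeric(m)
  beta[causal] <- sgn * mag
  structure(list(beta = beta, causal = causal), class = "effect_vector")
}

# Lower Cholesky factor of h2 R + (1 - h2) I, with eigenvalue clipping as a
# fallback for semi-definite R.
trait_chol <- function(h2, R) {
  n <- nrow(R)
  S <- h2 * R + (1 - h2) * diag(n)
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < -1e-8) stop("trait covariance is not PSD")
    L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  L
}

#' Simulate a quantitative trait
#'
#' Draws \eqn{y \sim N(G\beta,\; h^2 R + (1-h^2) I)} as \eqn{y = G\beta + Lz}
#' with \eqn{L L^T = h^2 R + (1-h^2) I} and standard-normal `z`. With
#' `beta = NULL` (or all zero) this is the null model; with `R = NULL` the
#' sample is unrelated and the covariance is the identity.
#'
#' @param region a [region_genotypes()] object (supplies `G` and `n`).
#' @param beta an [draw_effects()] result, a numeric effect vector, or `NULL`.
#' @param h2 heritability of the polygenic background.
#' @param R relationship matrix or `NULL` for unrelated samples.
#' @param L optional precomputed lower Cholesky factor of the covariance
#'   (reused across replicates).
#' @param seed optional seed.
#' @return Numeric trait vector of length `n`.
#' @export
simulate_trait <- function(region, beta = NULL, h2 = 0.29, R = NULL,
                           L = NULL, seed = NULL) {
  stopifnot(inherits(region, "region_genotypes"), h2 >= 0, h2 < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(region$G)
  mu <- if (is.null(beta)) numeric(n) else {
    b <- if (inherits(beta, "effect_vector")) beta$beta else as.numeric(beta)
    drop(region$G %*% b)
  }
  z <- stats::rnorm(n)
  if (is.null(R) && is.null(L)) return(mu + z)
  if (is.null(L)) L <- trait_chol(h2, R)
  mu + drop(L %*% z)
}

# ---------------------------------------------------------------------------
# Experiment engines. A panel of regions on one sample is prepared once; the
# relationship-matrix eigendecomposition, trait Cholesky factor and the
# rotated per-region functional designs are all cached, and replicates are
# processed in bulk. A dedicated test verifies that the engine reproduces
# flm_test() P values exactly.

#' Build a panel of synthetic regions on a common sample
#'
#' @param sample_type `"population"` (unrelated, `R = NULL`) or `"family"`
#'   (nuclear families).
#' @param n target sample size (rounded to whole families for `"family"`).
#' @param n_regions number of regions.
#' @param m_range inclusive range of variant counts per region.
#' @param n_offspring offspring per nuclear family.
#' @param sampler a [maf_sampler()].
#' @param min_rare minimum rare-variant count per region.
#' @param seed optional seed.
#' @return A list with `regions` (list of [region_genotypes()]), `R` (or
#'   `NULL`), `pedigree` (or `NULL`) and `n`.
#' @export
region_panel <- function(sample_type = c("population", "family"), n = 700L,
                         n_regions = 40L, m_range = c(30L, 60L),
                         n_offspring = 4L, sampler = maf_sampler(),
                         min_rare = 10L, seed = NULL) {
  sample_type <- match.arg(sample_type)
  if (!is.null(seed)) set.seed(seed)
  ms <- sample(seq(m_range[1L], m_range[2L]), n_regions, replace = TRUE)
  if (sample_type == "population") {
    regions <- lapply(seq_len(n_regions), function(r)
      simulate_population_genotypes(n, ms[r], sampler, min_rare = min_rare,
                                    region_id = sprintf("region%02d", r)))
    list(regions = regions, R = NULL, pedigree = NULL, n = as.integer(n))
  } else {
    fam_size <- 2L + n_offspring
    nf <- max(1L, round(n / fam_size))
    ped <- nuclear_pedigree(nf, n_offspring)
    R <- pedigree_relmatrix(ped)
    nn <- nrow(ped)
    regions <- lapply(seq_len(n_regions), function(r)
      gene_drop_region(ped, nn, ms[r], sampler, min_rare, 0.03, 10000L,
                       sprintf("region%02d", r)))
    list(regions = regions, R = R, pedigree = ped, n = nn)
  }
}

# Per-region cached quantities for the intercept-only engines.
prep_region_design <- function(region, weights, effect_spec, genotype_spec,
                               eig = NULL) {
  pos <- scale_positions(region$positions)
  sm <- build_smoother(pos, genotype_spec, effect_spec)
  w <- variant_weights(weights, region$mafs)
  Z <- region$G %*% (w * sm$W)
  n <- nrow(Z)
  if (is.null(eig)) {
    # unrelated: whitening is scalar; residualise on the intercept once
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    rg <- rank_guard(Zc)
    Q2 <- qr.Q(qr(rg$design))
    list(q = rg$rank, Q2 = Q2, n = n)
  } else {
    list(Zt = crossprod(eig$vectors, Z), n = n)
  }
}

# Family-sample F test in the rotated frame for intercept-only X.
# ytil, Xt, Zt are U' y, U' 1, U' Z; d the eigenvalues of R.
rotated_ftest <- function(ytil, Xt, Zt, d, h2) {
  sw <- 1 / sqrt(h2 * d + (1 - h2))
  ys <- ytil * sw
  Xs <- Xt * sw
  Zs <- Zt * sw
  xx <- sum(Xs^2)
  r0 <- ys - Xs * (sum(Xs * ys) / xx)
  Zres <- Zs - Xs %*% (crossprod(Xs, Zs) / xx)
  qz <- qr(Zres, tol = 1e-9)
  q <- qz$rank
  n <- length(ys)
  df2 <- n - 1L - q
  rss0 <- sum(r0^2)
  rss1 <- sum(qr.resid(qz, r0)^2)
  F_stat <- ((rss0 - rss1) / q) / (rss1 / df2)
  c(F_stat, q, df2, stats::pf(F_stat, q, df2, lower.tail = FALSE))
}

#' Type-I error experiment
#'
#' Simulates traits under the null (\eqn{\beta = 0}) over a panel of
#' synthetic regions, runs the weighted functional linear model test on every
#' replicate (replicates are assigned to panel regions in rotation), and
#' tabulates the proportion of P values at or below each requested
#' significance level, with binomial standard errors.
#'
#' Family-sample replicates each refit the null polygenic model by profiled
#' REML before testing, exactly as [flm_test()] would; the relationship
#' matrix eigendecomposition and the per-region functional designs are cached
#' across replicates.
#'
#' @param sample_type `"population"` or `"family"`.
#' @param n sample size.
#' @param n_replicates number of null replicates.
#' @param alphas significance levels to tabulate.
#' @param effect_spec,genotype_spec,weights model configuration, as in
#'   [flm_test()].
#' @param h2 heritability of the null trait for family samples (the
#'   unrelated-sample null trait is standard normal).
#' @param n_regions,m_range,n_offspring,min_rare panel configuration, see
#'   [region_panel()].
#' @param seed seed for the whole experiment.
#' @param keep if `TRUE`, store the panel and simulated traits for
#'   verification (memory-heavy; small runs only).
#' @return An object of class `"wflm_type1"`: `rates` (data.frame with
#'   `alpha`, `rate`, `se`), `p_values`, `region_index`, and configuration.
#' @export
run_type1 <- function(sample_type = c("population", "family"), n = 700L,
                      n_replicates = 1000L, alphas = c(0.05, 0.01),
                      effect_spec = basis_spec("bspline", 15),
                      genotype_spec = NULL,
                      weights = weight_spec("beta", 1, 25), h2 = 0.29,
                      n_regions = 40L, m_range = c(30L, 60L),
                      n_offspring = 4L, min_rare = 10L, seed = NULL,
                      keep = FALSE) {
  sample_type <- match.arg(sample_type)
  if (!is.null(seed)) set.seed(seed)
  panel <- region_panel(sample_type, n, n_regions, m_range, n_offspring,
                        min_rare = min_rare)
  nn <- panel$n
  B <- as.integer(n_replicates)
  region_index <- rep(seq_len(n_regions), length.out = B)
  cnt <- tabulate(region_index, n_regions)
  pvals <- numeric(B)
  traits <- if (keep) vector("list", n_regions)

  if (sample_type == "population") {
    prep <- lapply(panel$regions, prep_region_design, weights = weights,
                   effect_spec = effect_spec, genotype_spec = genotype_spec)
    for (r in seq_len(n_regions)) {
      if (cnt[r] == 0L) next
      Y <- matrix(stats::rnorm(nn * cnt[r]), nn, cnt[r])
      if (keep) traits[[r]] <- Y
      q <- prep[[r]]$q
      df2 <- nn - 1L - q
      num <- colSums(crossprod(prep[[r]]$Q2, Y)^2)
      rss0 <- colSums(Y^2) - nn * colMeans(Y)^2
      F_stat <- (num / q) / ((rss0 - num) / df2)
      pvals[region_index == r] <-
        stats::pf(F_stat, q, df2, lower.tail = FALSE)
    }
  } else {
    eig <- relmatrix_eigen(panel$R)
    d <- eig$values
    L <- trait_chol(h2, panel$R)
    Xt <- drop(crossprod(eig$vectors, rep(1, nn)))
    Xt <- matrix(Xt, nn, 1L)
    prep <- lapply(panel$regions, prep_region_design, weights = weights,
                   effect_spec = effect_spec, genotype_spec = genotype_spec,
                   eig = eig)
    for (r in seq_len(n_regions)) {
      if (cnt[r] == 0L) next
      Y <- L %*% matrix(stats::rnorm(nn * cnt[r]), nn, cnt[r])
      if (keep) traits[[r]] <- Y
      Yt <- crossprod(eig$vectors, Y)
      Zt <- prep[[r]]$Zt
      pr <- numeric(cnt[r])
      for (b in seq_len(cnt[r])) {
        ytil <- Yt[, b]
        h2hat <- profile_h2(ytil, Xt, d)
        pr[b] <- rotated_ftest(ytil, Xt[, 1L], Zt, d, h2hat)[4L]
      }
      pvals[region_index == r] <- pr
    }
  }
  rates <- data.frame(alpha = alphas,
                      rate = vapply(alphas, function(a) mean(pvals <= a),
                                    numeric(1)))
  rates$se <- sqrt(rates$rate * (1 - rates$rate) / B)
  structure(list(rates = rates, p_values = pvals,
                 region_index = region_index, sample_type = sample_type,
                 n = nn, n_replicates = B, effect_spec = effect_spec,
                 genotype_spec = genotype_spec, weights = weights, h2 = h2,
                 panel = if (keep) panel, traits = traits),
            class = "wflm_type1")
}

#' @export
print.wflm_type1 <- function(x, ...) {
  cat(sprintf("Type-I error: %s sample, n = %d, %d null replicates\n",
              x$sample_type, x$n, x$n_replicates))
  cat(sprintf("  basis %s%d, weights %s\n", x$effect_spec$family,
              x$effect_spec$K, format_weights(x$weights)))
  print(transform(x$rates, rate = signif(rate, 4), se = signif(se, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Power experiment
#'
#' Per replicate: a panel region is drawn uniformly, causal effects are drawn
#' under the scenario, a trait \eqn{y = G\beta + Lz} is simulated, the null
#' polygenic model is (re)fitted, and the weighted FLM test is run. Power is
#' the proportion of P values strictly below `threshold`.
#'
#' Several weight settings can be evaluated on the same replicates by passing
#' a list of [weight_spec()]s: trait generation consumes the random-number
#' stream identically regardless of weights, so settings are compared with
#' common random numbers.
#'
#' @param scenario a [sim_scenario()].
#' @param sample_type,n,effect_spec,genotype_spec,n_regions,m_range,
#'   n_offspring,min_rare,seed as in [run_type1()].
#' @param weights a [weight_spec()] or a (possibly named) list of them.
#' @param threshold significance threshold; the default `1e-3` suits
#'   moderate replicate counts (the conventional exome-wide threshold
#'   `2.5e-6` is available for large runs).
#' @return An object of class `"wflm_power"`: `power` (data.frame with one
#'   row per weight setting: `weights`, `power`, `se`), `p_values` (replicate
#'   x setting matrix), `threshold`, `scenario`.
#' @export
run_power <- function(scenario, sample_type = c("family", "population"),
                      n = 700L, effect_spec = basis_spec("bspline", 15),
                      genotype_spec = NULL,
                      weights = weight_spec("beta", 1, 25),
                      threshold = 1e-3, n_regions = 40L,
                      m_range = c(30L, 60L), n_offspring = 4L,
                      min_rare = 10L, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sample_type <- match.arg(sample_type)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(weights, "weight_spec")) weights <- list(weights)
  wlab <- names(weights) %||% vapply(weights, format_weights, character(1))
  panel <- region_panel(sample_type, n, n_regions, m_range, n_offspring,
                        min_rare = min_rare)
  nn <- panel$n
  fam <- sample_type == "family"
  if (fam) {
    eig <- relmatrix_eigen(panel$R)
    d <- eig$values
    L <- trait_chol(scenario$h2, panel$R)
    Xt <- matrix(drop(crossprod(eig$vectors, rep(1, nn))), nn, 1L)
  }
  # region x weight-setting design cache
  prep <- lapply(panel$regions, function(reg)
    lapply(weights, function(w)
      prep_region_design(reg, w, effect_spec, genotype_spec,
                         eig = if (fam) eig)))
  B <- scenario$n_replicates
  P <- matrix(NA_real_, B, length(weights),
              dimnames = list(NULL, wlab))
  for (b in seq_len(B)) {
    r <- sample.int(n_regions, 1L)
    reg <- panel$regions[[r]]
    eff <- draw_effects(reg, scenario)
    z <- stats::rnorm(nn)
    mu <- drop(reg$G %*% eff$beta)
    if (fam) {
      y <- mu + drop(L %*% z)
      ytil <- drop(crossprod(eig$vectors, y))
      h2hat <- profile_h2(ytil, Xt, d)
      for (k in seq_along(weights))
        P[b, k] <- rotated_ftest(ytil, Xt[, 1L], prep[[r]][[k]]$Zt, d,
                                 h2hat)[4L]
    } else {
      y <- mu + z
      rss0 <- sum(y^2) - nn * mean(y)^2
      for (k in seq_along(weights)) {
        pk <- prep[[r]][[k]]
        num <- sum(crossprod(pk$Q2, y)^2)
        df2 <- nn - 1L - pk$q
        F_stat <- (num / pk$q) / ((rss0 - num) / df2)
        P[b, k] <- stats::pf(F_stat, pk$q, df2, lower.tail = FALSE)
      }
    }
  }
  pow <- colMeans(P < threshold)
  res <- data.frame(weights = wlab, power = pow,
                    se = sqrt(pow * (1 - pow) / B), row.names = NULL)
  structure(list(power = res, p_values = P, threshold = threshold,
                 scenario = scenario, sample_type = sample_type, n = nn,
                 effect_spec = effect_spec),
            class = "wflm_power")
}

#' @export
print.wflm_power <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(paste0("Power: %s sample, n = %d, %d replicates, ",
                     "threshold %g\n"),
              x$sample_type, x$n, s$n_replicates, x$threshold))
  cat(sprintf("  scenario: %s pool, %s effects, s = %g, %g%% causal, %g%% same direction\n",
              s$causal_pool, s$effect_model, s$s, 100 * s$prop_causal,
              100 * s$prop_same_direction))
  print(transform(x$power, power = signif(power, 4), se = signif(se, 3)),
        row.names = FALSE)
  invisible(x)
}
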