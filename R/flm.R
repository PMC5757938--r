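#' Rank-revealing reduction of a design matrix
#'
#' Detects the numerical rank of a design by pivoted QR with relative
#' tolerance `1e-9` (scaled against the largest column norm) and returns the
#' full-rank column subset. Weighting combined with smoothing can make a
#' functional design rank deficient even when the nominal number of basis
#' functions is small; the test's numerator degrees of freedom must then use
#' the detected rank, not the nominal one.
#'
#' @param design numeric matrix.
#' @param tol relative rank tolerance.
#' @return A list with `design` (the retained columns), `rank`, and `kept`
#'   (the retained column indices).
#' @export
rank_guard <- function(design, tol = 1e-9) {
  design <- as.matrix(design)
  cn <- sqrt(colSums(design^2))
  if (!any(cn > 0))
    stop("design has rank 0 (weights or basis annihilated every column)")
  qrd <- qr(design, tol = tol)
  r <- qrd$rank
  if (r == 0L)
    stop("design has rank 0 (weights or basis annihilated every column)")
  kept <- sort(qrd$pivot[seq_len(r)])
  list(design = design[, kept, drop = FALSE], rank = r, kept = kept)
}

#' Weighted functional linear model test for one region
#'
#' Fits the weighted functional linear model
#' \deqn{y = X\alpha + G \Theta W \beta_F + h + \epsilon}
#' and tests \eqn{H_0: \beta_F = 0} against \eqn{H_1: \beta_F \neq 0} with an
#' F-statistic for fixed effects in the mixed model. \eqn{G} is the dosage
#' matrix of the region, \eqn{\Theta} the diagonal matrix of variant weights
#' (e.g. beta-density functions of MAF), and \eqn{W} the smoother matrix
#' built from the basis specifications.
#'
#' The variance components come from a null-model fit (computed here if not
#' supplied) and are held fixed; data are whitened by \eqn{\Omega^{-1/2}} and
#' the test reduces to a nested ordinary-least-squares comparison:
#' \deqn{F = \frac{(RSS_0 - RSS_1)/q}{RSS_1/(n - p_0 - q)},}
#' where \eqn{q} is the detected rank of the whitened, covariate-adjusted
#' functional design and \eqn{p_0} the number of fixed covariates including
#' the intercept. For unrelated samples this is exactly the classical
#' multiple-regression F-test on the functional design.
#'
#' @param region a [region_genotypes()] object.
#' @param data a [phenotype_data()] object, sample-aligned with `region`.
#' @param fit optional `"wflm_null"` fit from [fit_null()]; if `NULL` an
#'   unrelated-sample null model is fitted.
#' @param genotype_spec [basis_spec()] for genotype smoothing, or `NULL`
#'   (default) for the beta-smooth-only model.
#' @param effect_spec [basis_spec()] for effect smoothing.
#' @param weights a [weight_spec()]; default Beta(MAF; 1, 25) density weights.
#' @return An object of class `"wflm"`: the association result with fields
#'   `region_id`, `n`, `m_variants`, `K_beta_used`, `rank_used`, `F_stat`,
#'   `df1`, `df2`, `p_value`, `beta_F_hat`, `notes`, plus the specs used.
#' @examples
#' set.seed(1)
#' reg <- simulate_population_genotypes(n = 300, m = 30)
#' dat <- phenotype_data(simulate_trait(reg))
#' flm_test(reg, dat, effect_spec = basis_spec("bspline", 15))
#' @export
flm_test <- function(region, data, fit = NULL, genotype_spec = NULL,
                     effect_spec = basis_spec("bspline", 15),
                     weights = weight_spec("beta", 1, 25)) {
  stopifnot(inherits(region, "region_genotypes"),
            inherits(data, "phenotype_data"),
            inherits(weights, "weight_spec"))
  n <- length(data$y)
  if (nrow(region$G) != n)
    stop("region and phenotype data have different sample sizes; ",
         "align them first (see align_samples)")
  if (!is.null(region$ids) && !is.null(data$ids) &&
      !identical(as.character(region$ids), as.character(data$ids)))
    stop("sample ids of region and phenotype data disagree; ",
         "align them first (see align_samples)")
  if (is.null(fit)) fit <- fit_null(data)
  stopifnot(inherits(fit, "wflm_null"))
  if (fit$n != n) stop("null-model fit does not match the sample size")

  pos <- scale_positions(region$positions)
  sm <- build_smoother(pos, genotype_spec, effect_spec)
  w <- variant_weights(weights, region$mafs)
  Z <- region$G %*% (w * sm$W)           # G Theta W

  yw <- decorrelate(fit, data$y)
  Xw <- decorrelate(fit, data$X)
  Zw <- decorrelate(fit, Z)

  qx <- qr(Xw)
  p0 <- ncol(Xw)
  Zr <- qr.resid(qx, Zw)
  rg <- rank_guard(Zr)
  q <- rg$rank
  df2 <- n - p0 - q
  if (df2 <= 0L)
    stop("overparametrized model: n - p0 - q = ", df2, " <= 0")

  r0 <- qr.resid(qx, yw)
  qz <- qr(rg$design)
  rss0 <- sum(r0^2)
  rss1 <- sum(qr.resid(qz, r0)^2)
  F_stat <- ((rss0 - rss1) / q) / (rss1 / df2)
  p_value <- stats::pf(F_stat, q, df2, lower.tail = FALSE)

  beta_F <- rep(NA_real_, ncol(Zw))
  beta_F[rg$kept] <- drop(qr.coef(qz, r0))
  names(beta_F) <- paste0("betaF", seq_along(beta_F))

  notes <- sm$notes
  if (q < ncol(Zw))
    notes <- c(notes, sprintf("design rank %d < K_beta %d; df1 uses rank",
                              q, ncol(Zw)))
  structure(list(region_id = region$region_id, n = n,
                 m_variants = ncol(region$G),
                 K_beta_used = sm$effect_spec$K, rank_used = q,
                 F_stat = F_stat, df1 = q, df2 = df2, p_value = p_value,
                 beta_F_hat = beta_F, notes = notes,
                 effect_spec = sm$effect_spec,
                 genotype_spec = sm$genotype_spec, weights = weights,
                 h2 = fit$h2),
            class = "wflm")
}

#' @export
print.wflm <- function(x, ...) {
  cat("Weighted functional linear model test\n")
  cat(sprintf("  region: %s  (n = %d, m = %d variants)\n",
              x$region_id %||% "(unnamed)", x$n, x$m_variants))
  cat(sprintf("  basis: %s K = %d%s; weights: %s\n",
              x$effect_spec$family, x$K_beta_used,
              if (is.null(x$genotype_spec)) " (beta-smooth only)" else
                sprintf(" (genotype basis %s K = %d)",
                        x$genotype_spec$family, x$genotype_spec$K),
              format_weights(x$weights)))
  cat(sprintf("  F = %.4f on (%d, %d) df,  P = %.4g\n",
              x$F_stat, x$df1, x$df2, x$p_value))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @export
summary.wflm <- function(object, ...) {
  print(object)
  if (!all(is.na(object$beta_F_hat))) {
    cat("  basis-coefficient estimates (whitened design):\n")
    print(signif(object$beta_F_hat, 4))
  }
  invisible(object)
}

#' @export
coef.wflm <- function(object, ...) object$beta_F_hat

#' Collect association results into a data frame
#'
#' @param results a `"wflm"` object or a list of them.
#' @return A data.frame with one row per region: `region_id`, `n`, `m`,
#'   `K_beta_used`, `df1`, `df2`, `F`, `P`, `weights`, `basis`.
#' @export
results_table <- function(results) {
  if (inherits(results, "wflm")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(region_id = r$region_id %||% NA_character_, n = r$n,
               m = r$m_variants, K_beta_used = r$K_beta_used,
               df1 = r$df1, df2 = r$df2, F = r$F_stat, P = r$p_value,
               weights = format_weights(r$weights),
               basis = paste0(r$effect_spec$family, r$K_beta_used),
               stringsAsFactors = FALSE)
  }))
}
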