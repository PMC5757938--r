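#' Variant weight specification
#'
#' Describes how per-variant weights (the diagonal of the weight matrix
#' \eqn{\Theta}) are obtained. The standard choice weights each variant by the
#' beta distribution density evaluated at its minor-allele frequency,
#' \eqn{Beta(MAF_j; a_1, a_2)}: with \eqn{a_1 \le 1} and \eqn{a_2 \ge 1} rarer
#' variants receive larger weights. `(1, 1)` gives every variant weight 1 and
#' reproduces the unweighted model exactly; `(1, 25)` is the usual
#' rare-variant weighting and `(0.5, 0.5)` a milder alternative.
#'
#' The literature writes \eqn{\sqrt{w_j} = Beta(MAF_j; a_1, a_2)} while the
#' model design multiplies genotypes by \eqn{\Theta} once; both readings are
#' supported via `convention`: `"density"` (default) sets
#' \eqn{\Theta_{jj}} to the beta density itself, `"squared"` to its square.
#' For a saturated effect basis the two differ only by column scaling and give
#' identical tests; for smoothed designs the choice matters, hence the switch.
#'
#' @param type `"beta"`, `"none"` (all weights 1), or `"custom"`.
#' @param a1,a2 beta shape parameters, both > 0 (type `"beta"`).
#' @param convention `"density"` or `"squared"`, see Details.
#' @param weights nonnegative per-variant weights (type `"custom"`).
#' @return An object of class `"weight_spec"`.
#' @export
weight_spec <- function(type = c("beta", "none", "custom"), a1 = 1, a2 = 25,
                        convention = c("density", "squared"), weights = NULL) {
  type <- match.arg(type)
  convention <- match.arg(convention)
  if (type == "beta" && (a1 <= 0 || a2 <= 0))
    stop("beta shape parameters a1, a2 must be > 0")
  if (type == "custom") {
    if (is.null(weights) || any(!is.finite(weights)) || any(weights < 0))
      stop("custom weights must be finite and nonnegative")
  }
  structure(list(type = type, a1 = a1, a2 = a2, convention = convention,
                 weights = weights), class = "weight_spec")
}

#' @export
print.weight_spec <- function(x, ...) {
  cat("Weights:", switch(x$type,
                         beta = sprintf("Beta(MAF; %g, %g) [%s]", x$a1, x$a2,
                                        x$convention),
                         none = "none (unweighted)",
                         custom = "custom per-variant"), "\n")
  invisible(x)
}

# Short label for result tables.
format_weights <- function(spec) {
  switch(spec$type,
         beta = sprintf("beta(%g,%g)%s", spec$a1, spec$a2,
                        if (spec$convention == "squared") "^2" else ""),
         none = "none",
         custom = "custom")
}

#' Beta-density variant weights
#'
#' Computes \eqn{Beta(MAF_j; a_1, a_2)}, the beta distribution density
#' evaluated at each minor-allele frequency, i.e.
#' \eqn{MAF^{a_1-1}(1-MAF)^{a_2-1} / B(a_1, a_2)}. These form the diagonal of
#' the variant weight matrix \eqn{\Theta}.
#'
#' @param mafs minor-allele frequencies, strictly in (0, 0.5]. Monomorphic
#'   variants must be removed before weighting.
#' @param a1,a2 beta shape parameters, both > 0.
#' @return Numeric vector of weights, one per variant.
#' @examples
#' beta_weights(0.03, 1, 25)   # 25 * 0.97^24
#' beta_weights(0.5, 0.5, 0.5) # 2 / pi
#' @export
beta_weights <- function(mafs, a1, a2) {
  if (a1 <= 0 || a2 <= 0) stop("beta shape parameters a1, a2 must be > 0")
  mafs <- as.numeric(mafs)
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs > 0.5))
    stop("MAFs must lie strictly in (0, 0.5]")
  stats::dbeta(mafs, a1, a2)
}

# Resolve a weight_spec against a region's MAFs -> diagonal of Theta.
variant_weights <- function(spec, mafs) {
  m <- length(mafs)
  switch(spec$type,
         none = rep(1, m),
         beta = {
           w <- beta_weights(mafs, spec$a1, spec$a2)
           if (spec$convention == "squared") w^2 else w
         },
         custom = {
           if (length(spec$weights) != m)
             stop("custom weights length (", length(spec$weights),
                  ") does not match number of variants (", m, ")")
           spec$weights
         })
}

#' Filter a region by minor-allele frequency
#'
#' Returns the sub-region containing only variants with `MAF <= threshold`,
#' the filtering technique in which common variants are excluded from a
#' region before testing. (Weighting is the soft alternative to this hard
#' exclusion.)
#'
#' @param region a [region_genotypes()] object.
#' @param threshold MAF cutoff in (0, 0.5]; the conventional rare-variant
#'   cutoff is 0.03.
#' @return A `region_genotypes` object restricted to the surviving variants.
#' @export
maf_filter <- function(region, threshold) {
  stopifnot(inherits(region, "region_genotypes"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 0.5)
    stop("threshold must lie in (0, 0.5]")
  keep <- region$mafs <= threshold
  if (!any(keep))
    stop("no variants with MAF <= ", threshold, " in region ",
         region$region_id %||% "", " (empty region)")
  region_genotypes(region$G[, keep, drop = FALSE], region$positions[keep],
                   ids = region$ids, region_id = region$region_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
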