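#' Region genotype container
#'
#' Holds the dosage matrix, variant positions and minor-allele frequencies for
#' one genomic region. Construction performs the standard QC for dosage-based
#' region tests: missing dosages are mean-imputed per variant (which preserves
#' the allele frequency), dosages are re-polarised so that columns count the
#' minor allele in the analysed sample, monomorphic variants are dropped, and
#' variants are sorted by position.
#'
#' @param G `n x m` dosage matrix (minor- or alt-allele counts in `{0, 1, 2}`,
#'   `NA` allowed).
#' @param positions base-pair coordinate per variant (length `m`).
#' @param ids optional sample identifiers (length `n`).
#' @param region_id optional region label.
#' @return An object of class `"region_genotypes"` with fields `ids`,
#'   `positions`, `G`, `mafs`, `region_id`.
#' @export
region_genotypes <- function(G, positions, ids = NULL, region_id = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (length(positions) != ncol(G))
    stop("length(positions) must equal ncol(G)")
  if (!is.null(ids) && length(ids) != nrow(G))
    stop("length(ids) must equal nrow(G)")
  ord <- order(positions)
  G <- G[, ord, drop = FALSE]
  positions <- as.numeric(positions[ord])
  # mean-impute missing dosages per variant
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0L)) {
      mu <- mean(G[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      G[is.na(G[, j]), j] <- mu
    }
  }
  p <- colMeans(G) / 2
  flip <- p > 0.5
  if (any(flip)) {
    G[, flip] <- 2 - G[, flip]
    p[flip] <- 1 - p[flip]
  }
  mono <- p <= 0
  if (any(mono)) {
    if (all(mono)) stop("all variants are monomorphic in region ",
                        region_id %||% "")
    warning(sum(mono), " monomorphic variant(s) dropped from region ",
            region_id %||% "", call. = FALSE)
    G <- G[, !mono, drop = FALSE]
    positions <- positions[!mono]
    p <- p[!mono]
  }
  structure(list(ids = ids, positions = positions, G = G, mafs = p,
                 region_id = region_id), class = "region_genotypes")
}

#' @export
print.region_genotypes <- function(x, ...) {
  cat("Region", x$region_id %||% "(unnamed)", ":", nrow(x$G), "samples,",
      ncol(x$G), "variants, positions", min(x$positions), "-",
      max(x$positions), "\n")
  cat("  MAF range:", signif(min(x$mafs), 3), "-", signif(max(x$mafs), 3),
      ";", sum(x$mafs <= 0.03), "rare (MAF <= 0.03)\n")
  invisible(x)
}

#' @export
dim.region_genotypes <- function(x) dim(x$G)

#' Phenotype and covariate container
#'
#' Builds the trait vector `y` and the fixed-effect design `X` whose first
#' column is the intercept. The design must have full column rank (a constant
#' covariate, for example, is rejected rather than silently aliased).
#'
#' @param y numeric trait vector, no missing values.
#' @param covariates optional numeric matrix or data.frame of covariates
#'   (no intercept column; one is prepended).
#' @param ids optional sample identifiers.
#' @return An object of class `"phenotype_data"` with fields `y`, `X`, `ids`.
#' @export
phenotype_data <- function(y, covariates = NULL, ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing trait values; drop incomplete rows first")
  if (is.null(covariates)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    if (nrow(C) != n) stop("covariates must have one row per sample")
    if (anyNA(C)) stop("missing covariate values; drop incomplete rows first")
    X <- cbind("(Intercept)" = 1, C)
  }
  if (qr(X)$rank < ncol(X))
    stop("covariate design is rank deficient (constant or collinear columns)")
  if (!is.null(ids) && length(ids) != n)
    stop("length(ids) must equal length(y)")
  structure(list(y = y, X = X, ids = ids), class = "phenotype_data")
}

#' @export
print.phenotype_data <- function(x, ...) {
  cat("Phenotypes:", length(x$y), "samples,", ncol(x$X) - 1L, "covariate(s)\n")
  invisible(x)
}

#' Align genotypes, phenotypes and relationship matrix by sample ID
#'
#' Intersects the sample identifiers of a region, a phenotype table and
#' (optionally) a relationship matrix, and reorders every object to the common
#' ID order. Any misalignment is an error, never silent.
#'
#' @param region a [region_genotypes()] object with non-`NULL` `ids`.
#' @param data a [phenotype_data()] object with non-`NULL` `ids`.
#' @param R optional relationship matrix with row/col names.
#' @return A list with the aligned `region`, `data` and `R` (or `NULL`).
#' @export
align_samples <- function(region, data, R = NULL) {
  if (is.null(region$ids) || is.null(data$ids))
    stop("both region and phenotype data must carry sample ids to align")
  common <- intersect(data$ids, region$ids)
  if (!is.null(R)) {
    if (is.null(rownames(R))) stop("relationship matrix must carry sample ids")
    common <- intersect(common, rownames(R))
  }
  if (length(common) < 2L)
    stop("fewer than 2 samples shared between genotypes, phenotypes",
         if (!is.null(R)) " and relationship matrix")
  gi <- match(common, region$ids)
  pi <- match(common, data$ids)
  region2 <- region_genotypes(region$G[gi, , drop = FALSE], region$positions,
                              ids = common, region_id = region$region_id)
  data2 <- phenotype_data(data$y[pi],
                          if (ncol(data$X) > 1L)
                            data$X[pi, -1L, drop = FALSE],
                          ids = common)
  R2 <- if (!is.null(R)) R[common, common, drop = FALSE]
  list(region = region2, data = data2, R = R2)
}
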