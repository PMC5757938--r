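# Null polygenic model: y = X alpha + h + e, h ~ N(0, sg2 R), e ~ N(0, se2 I),
# so Omega = sg2 R + se2 I. With R = U D U' the restricted likelihood profiles
# to a 1-D search over h2 = sg2 / (sg2 + se2): in the rotated frame the model
# is heteroscedastic least squares with variances proportional to
# V_i = h2 d_i + (1 - h2).

# Restricted log-likelihood at h2 (sigma^2 profiled out), rotated data.
# Returns list(loglik, alpha, sigma2) or loglik only when value_only.
reml_at_h2 <- function(h2, ytil, Xtil, d, value_only = TRUE) {
  n <- length(ytil); p <- ncol(Xtil)
  V <- h2 * d + (1 - h2)
  if (any(V <= 1e-12)) return(if (value_only) -Inf else NULL)
  w <- 1 / V
  XtWX <- crossprod(Xtil, Xtil * w)
  XtWy <- crossprod(Xtil, ytil * w)
  alpha <- solve(XtWX, XtWy)
  rss <- sum(ytil^2 * w) - sum(XtWy * alpha)
  sigma2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + sum(log(V)) +
                  determinant(XtWX, logarithm = TRUE)$modulus[1L])
  if (value_only) ll else list(loglik = ll, alpha = drop(alpha),
                               sigma2 = sigma2, h2 = h2)
}

# Profiled REML search over h2 in [0, 1], guarding boundary optima that a
# unimodal interior search can miss.
profile_h2 <- function(ytil, Xtil, d, tol = 1e-8) {
  opt <- stats::optimize(reml_at_h2, c(0, 1), maximum = TRUE, tol = tol,
                         ytil = ytil, Xtil = Xtil, d = d)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective,
            reml_at_h2(0, ytil, Xtil, d),
            reml_at_h2(1, ytil, Xtil, d))
  cand[which.max(vals)]
}

# Eigendecomposition of R with PSD clipping; reusable across regions and
# replicates (R never changes within a sample).
relmatrix_eigen <- function(R) {
  if (max(abs(R - t(R))) > 1e-10)
    stop("relationship matrix is not symmetric")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("relationship matrix is not positive semi-definite (min eigenvalue ",
         signif(min(e$values), 3), ")")
  e$values[e$values < 0] <- 0
  e
}

#' Fit the null polygenic model
#'
#' Estimates the variance components of
#' \eqn{y = X\alpha + h + \epsilon}, \eqn{h \sim N(0, \sigma_g^2 R)},
#' \eqn{\epsilon \sim N(0, \sigma_e^2 I)}, by restricted maximum likelihood.
#' The covariance \eqn{\Omega = \sigma_g^2 R + \sigma_e^2 I} is
#' eigendecomposed once (\eqn{R = U D U^T}) and the restricted likelihood is
#' profiled down to a bounded 1-D search over the heritability
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2) \in [0, 1]}.
#'
#' For an unrelated sample (`R = NULL`, or numerically the identity) the two
#' components are not separately identifiable; by convention the fit reports
#' \eqn{\sigma_g^2 = 0} with the total variance in \eqn{\sigma_e^2}.
#'
#' The fit is intended to be computed once per trait and held fixed across
#' regions (`eigen_R` lets the caller reuse the eigendecomposition across
#' traits on the same sample).
#'
#' @param data a [phenotype_data()] object.
#' @param R relationship matrix (expected additive relationship, 2 x kinship,
#'   diagonal 1 for outbred individuals), or `NULL` for unrelated samples.
#' @param eigen_R optional precomputed `eigen(R, symmetric = TRUE)` result.
#' @param tol convergence tolerance of the profiled search over \eqn{h^2}.
#' @return An object of class `"wflm_null"` with components `alpha_hat`,
#'   `sigma_g2`, `sigma_e2`, `h2`, `loglik`, `eig` (or `NULL`), `identity`,
#'   `n`, `p`.
#' @export
fit_null <- function(data, R = NULL, eigen_R = NULL, tol = 1e-8) {
  stopifnot(inherits(data, "phenotype_data"))
  y <- data$y; X <- data$X
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need more samples than fixed-effect parameters")
  if (stats::var(y) < .Machine$double.eps)
    stop("trait has zero variance")
  if (qr(X)$rank < p) stop("covariate design is rank deficient")

  identity <- is.null(R) && is.null(eigen_R)
  if (!identity && is.null(eigen_R) && max(abs(R - diag(n))) < 1e-12)
    identity <- TRUE
  if (identity) {
    qx <- qr(X)
    res <- qr.resid(qx, y)
    sigma2 <- sum(res^2) / (n - p)
    alpha <- drop(qr.coef(qx, y))
    # same constant convention as reml_at_h2 evaluated at V = I
    ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) +
                    determinant(crossprod(X), logarithm = TRUE)$modulus[1L])
    fit <- list(alpha_hat = alpha, sigma_g2 = 0, sigma_e2 = sigma2, h2 = 0,
                loglik = ll, eig = NULL, identity = TRUE, n = n, p = p,
                ids = data$ids)
    class(fit) <- "wflm_null"
    return(fit)
  }

  e <- if (is.null(eigen_R)) relmatrix_eigen(R) else eigen_R
  if (length(e$values) != n) stop("relationship matrix not conformable with y")
  U <- e$vectors; d <- e$values
  ytil <- crossprod(U, y)
  Xtil <- crossprod(U, X)
  h2 <- profile_h2(ytil, Xtil, d, tol)
  at <- reml_at_h2(h2, ytil, Xtil, d, value_only = FALSE)
  fit <- list(alpha_hat = at$alpha, sigma_g2 = h2 * at$sigma2,
              sigma_e2 = (1 - h2) * at$sigma2, h2 = h2, loglik = at$loglik,
              eig = e, identity = FALSE, n = n, p = p, ids = data$ids)
  class(fit) <- "wflm_null"
  fit
}

#' @export
print.wflm_null <- function(x, ...) {
  cat("Null polygenic model (REML)\n")
  cat(sprintf("  n = %d, fixed effects = %d\n", x$n, x$p))
  cat(sprintf("  sigma_g^2 = %.6g, sigma_e^2 = %.6g, h^2 = %.4f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  if (x$identity)
    cat("  (unrelated sample: R = I, components not separable)\n")
  cat(sprintf("  restricted logLik = %.4f\n", x$loglik))
  invisible(x)
}

#' @export
coef.wflm_null <- function(object, ...) object$alpha_hat

#' @export
logLik.wflm_null <- function(object, ...) {
  structure(object$loglik, df = object$p + if (object$identity) 1L else 2L,
            class = "logLik")
}

#' Whiten a matrix by the inverse square root of the fitted covariance
#'
#' Computes \eqn{\Omega^{-1/2} M} through the stored eigendecomposition, with
#' \eqn{\Omega = \sigma_g^2 R + \sigma_e^2 I} from a null-model fit. After the
#' transform the model errors are exchangeable with unit variance, so ordinary
#' least squares applies.
#'
#' @param fit a `"wflm_null"` object from [fit_null()].
#' @param M numeric vector or `n x k` matrix.
#' @return The whitened vector/matrix, same shape as `M`.
#' @export
decorrelate <- function(fit, M) {
  stopifnot(inherits(fit, "wflm_null"))
  vec <- is.null(dim(M))
  M <- as.matrix(M)
  if (nrow(M) != fit$n) stop("M not conformable with the fitted sample")
  if (fit$identity) {
    if (fit$sigma_e2 <= 0) stop("singular covariance (zero variance)")
    out <- M / sqrt(fit$sigma_e2)
  } else {
    V <- fit$sigma_g2 * fit$eig$values + fit$sigma_e2
    if (any(V <= 0)) stop("singular covariance Omega; cannot whiten")
    out <- fit$eig$vectors %*% (crossprod(fit$eig$vectors, M) / sqrt(V))
  }
  if (vec) drop(out) else out
}
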