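#' Basis specification for functional smoothing
#'
#' Describes the set of basis functions used to smooth genotypes and/or their
#' effects along a genomic region. Two families are supported: cubic (or
#' general order) B-splines with uniformly spaced interior knots, and the
#' Fourier system on period 1. These are the two standard choices for
#' functional region-based association models (typically 15 B-spline or 25
#' Fourier basis functions).
#'
#' @param family `"bspline"` or `"fourier"`.
#' @param K number of basis functions. Must be odd for the Fourier family
#'   (the constant plus sine/cosine pairs) and at least `order` for B-splines.
#' @param order spline order (B-splines only); 4 = cubic, the default.
#' @return An object of class `"basis_spec"`.
#' @examples
#' basis_spec("bspline", 15)
#' basis_spec("fourier", 25)
#' @export
basis_spec <- function(family = c("bspline", "fourier"), K, order = 4L) {
  family <- match.arg(family)
  K <- as.integer(K)
  if (K < 1L) stop("K must be a positive integer")
  if (family == "fourier") {
    if (K %% 2L == 0L)
      stop("Fourier basis requires odd K (constant + sine/cosine pairs)")
  } else {
    order <- as.integer(order)
    if (order < 1L) stop("spline order must be >= 1")
    if (K < order) stop("B-spline basis requires K >= order (K=", K,
                        ", order=", order, ")")
  }
  structure(list(family = family, K = K,
                 order = if (family == "bspline") order else NA_integer_),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("Basis:", x$family, "K =", x$K,
      if (x$family == "bspline") paste0("(order ", x$order, ")") else "", "\n")
  invisible(x)
}

#' Scale variant positions to the unit interval
#'
#' Maps base-pair coordinates of the variants in a region affinely from
#' \eqn{[t_1, t_m]} to \eqn{[0, 1]}. Positions are sorted ascending first.
#' Duplicate positions (e.g. multiple alleles annotated at one coordinate)
#' would make the functional representation ill-defined, so within each run of
#' duplicates the k-th occurrence is shifted by \eqn{k \epsilon} with
#' \eqn{\epsilon} equal to 1e-6 of the raw span, deterministically, before
#' scaling.
#'
#' @param raw_positions integer (or numeric) base-pair coordinates, length
#'   >= 2.
#' @return A list of class `"position_map"` with components `raw` (sorted,
#'   jittered coordinates), `scaled` (in `[0, 1]`) and `order` (the permutation
#'   applied to the input).
#' @examples
#' scale_positions(c(100, 200, 300))$scaled  # 0, 0.5, 1
#' @export
scale_positions <- function(raw_positions) {
  if (length(raw_positions) < 2L) stop("need at least 2 variant positions")
  ord <- order(raw_positions)
  t <- as.numeric(raw_positions[ord])
  span <- t[length(t)] - t[1L]
  if (span <= 0)
    stop("degenerate region: all variant positions are identical")
  if (anyDuplicated(t)) {
    eps <- 1e-6 * span
    # occurrence index within each run of equal positions: 0, 1, 2, ...
    k <- stats::ave(t, t, FUN = function(v) seq_along(v) - 1)
    t <- t + k * eps
    span <- t[length(t)] - t[1L]
  }
  scaled <- (t - t[1L]) / span
  structure(list(raw = t, scaled = scaled, order = ord),
            class = "position_map")
}

#' Evaluate the Fourier basis
#'
#' Columns are the constant function 1 followed by
#' \eqn{\sqrt{2}\sin(2\pi k t), \sqrt{2}\cos(2\pi k t)} pairs, which are
#' orthonormal on \eqn{[0, 1]}. Orthonormality makes the cross-integral of two
#' Fourier bases the identity; downstream test statistics are invariant to the
#' normalisation, which is chosen purely for this analytic convenience.
#'
#' @param t evaluation points in `[0, 1]`.
#' @param K odd number of basis functions.
#' @return `length(t) x K` matrix.
#' @export
fourier_basis <- function(t, K) {
  K <- as.integer(K)
  if (K < 1L || K %% 2L == 0L) stop("Fourier basis requires odd K >= 1")
  t <- as.numeric(t)
  B <- matrix(0, length(t), K)
  B[, 1L] <- 1
  s2 <- sqrt(2)
  for (k in seq_len((K - 1L) %/% 2L)) {
    B[, 2L * k]      <- s2 * sin(2 * pi * k * t)
    B[, 2L * k + 1L] <- s2 * cos(2 * pi * k * t)
  }
  B
}

# Knot vector for K B-spline basis functions of given order on [0, 1]:
# boundary knots repeated `order` times, K - order equally spaced simple
# interior knots ("uniform distribution of knots").
bspline_knots <- function(K, order) {
  n_int <- K - order
  interior <- if (n_int > 0L) seq(0, 1, length.out = n_int + 2L)[-c(1L, n_int + 2L)]
  c(rep(0, order), interior, rep(1, order))
}

#' Evaluate the B-spline basis
#'
#' B-splines of the given order with boundary knots at 0 and 1 repeated
#' `order` times and `K - order` equally spaced simple interior knots. Rows
#' form a partition of unity (they sum to 1) and all entries are nonnegative.
#'
#' @param t evaluation points in `[0, 1]`.
#' @param K number of basis functions, `K >= order`.
#' @param order spline order (4 = cubic).
#' @return `length(t) x K` matrix.
#' @export
bspline_basis <- function(t, K, order = 4L) {
  K <- as.integer(K); order <- as.integer(order)
  if (K < order) stop("B-spline basis requires K >= order")
  t <- as.numeric(t)
  if (any(t < 0 | t > 1)) stop("evaluation points must lie in [0, 1]")
  splines::splineDesign(bspline_knots(K, order), t, ord = order)
}

# Evaluate a basis_spec at points t.
basis_matrix <- function(spec, t) {
  switch(spec$family,
         fourier = fourier_basis(t, spec$K),
         bspline = bspline_basis(t, spec$K, spec$order))
}

# Cross-integral J = \int_0^1 phi(t) psi(t)^T dt between two bases.
# Fourier x Fourier is analytic (orthonormal system): J has ones on the
# diagonal. Any pair involving B-splines is integrated by composite
# Gauss-Legendre quadrature with 7 points per inter-knot interval, exact for
# products of the piecewise polynomials in play and accurate far below 1e-10
# for the trigonometric factors at these interval widths.
cross_integral <- function(spec1, spec2) {
  if (spec1$family == "fourier" && spec2$family == "fourier") {
    J <- matrix(0, spec1$K, spec2$K)
    diag(J)[seq_len(min(spec1$K, spec2$K))] <- 1
    return(J)
  }
  brk <- c(0, 1)
  for (s in list(spec1, spec2))
    if (s$family == "bspline") {
      kn <- bspline_knots(s$K, s$order)
      brk <- c(brk, kn[kn > 0 & kn < 1])
    }
  brk <- sort(unique(brk))
  nodes <- numeric(0); wts <- numeric(0)
  for (i in seq_len(length(brk) - 1L)) {
    gl <- pracma::gaussLegendre(7L, brk[i], brk[i + 1L])
    nodes <- c(nodes, gl$x); wts <- c(wts, gl$w)
  }
  P1 <- basis_matrix(spec1, nodes)
  P2 <- basis_matrix(spec2, nodes)
  crossprod(P1 * wts, P2)
}

# Reduce K to the largest valid value <= m for the family (odd for Fourier,
# >= order for B-spline). Guards against overparametrised regions with fewer
# variants than basis functions.
reduce_spec <- function(spec, m) {
  if (spec$K <= m) return(spec)
  if (spec$family == "fourier") {
    K <- if (m %% 2L == 1L) m else m - 1L
    if (K < 1L) stop("region too small for any Fourier basis")
  } else {
    K <- m
    if (K < spec$order)
      stop("region has fewer variants (", m, ") than the spline order (",
           spec$order, ")")
  }
  basis_spec(spec$family, K, if (spec$family == "bspline") spec$order else 4L)
}

#' Build the smoother matrix for a region
#'
#' Assembles the \eqn{m \times K_\beta} smoother matrix \eqn{W} that converts
#' the raw genotype design into basis-coefficient space. With genotype
#' smoothing (`genotype_spec` supplied),
#' \deqn{W = \Phi (\Phi^T \Phi)^{-1} \int_0^1 \phi(t) \psi^T(t)\,dt,}
#' where \eqn{\Phi} evaluates the genotype basis at the scaled variant
#' positions and \eqn{\psi} is the effect basis. In the beta-smooth-only model
#' (`genotype_spec = NULL`) only the effects are expanded and \eqn{W} is the
#' effect-basis evaluation matrix itself. When the two bases are identical the
#' two constructions span the same design space and yield identical tests.
#'
#' If the requested number of effect (or genotype) basis functions exceeds the
#' number of variants, it is reduced to the largest valid value and the
#' reduction is recorded in `notes`.
#'
#' @param pos a `"position_map"` from [scale_positions()].
#' @param genotype_spec a [basis_spec()] for smoothing genotypes, or `NULL`
#'   for the beta-smooth-only model.
#' @param effect_spec a [basis_spec()] for smoothing the genetic effects.
#' @return A list of class `"smoother"` with components `W`, `Phi`,
#'   `Psi_eval`, `J`, `effect_spec`, `genotype_spec`, `notes`.
#' @export
build_smoother <- function(pos, genotype_spec = NULL, effect_spec) {
  stopifnot(inherits(pos, "position_map"), inherits(effect_spec, "basis_spec"))
  m <- length(pos$scaled)
  notes <- character(0)
  es <- reduce_spec(effect_spec, m)
  if (es$K != effect_spec$K)
    notes <- c(notes, sprintf("K_beta reduced from %d to %d (m = %d variants)",
                              effect_spec$K, es$K, m))
  Psi <- basis_matrix(es, pos$scaled)
  if (is.null(genotype_spec)) {
    return(structure(list(W = Psi, Phi = NULL, Psi_eval = Psi, J = NULL,
                          effect_spec = es, genotype_spec = NULL,
                          notes = notes), class = "smoother"))
  }
  stopifnot(inherits(genotype_spec, "basis_spec"))
  gs <- reduce_spec(genotype_spec, m)
  if (gs$K != genotype_spec$K)
    notes <- c(notes, sprintf("K_G reduced from %d to %d (m = %d variants)",
                              genotype_spec$K, gs$K, m))
  Phi <- basis_matrix(gs, pos$scaled)
  PtP <- crossprod(Phi)
  # refuse ill-conditioned Grams: the inverse would be numerically meaningless
  if (rcond(PtP) < 1e-10)
    stop("Phi^T Phi is numerically singular (m = ", m, ", K_G = ", gs$K,
         "); use the beta-smooth-only model (genotype_spec = NULL) ",
         "or fewer genotype basis functions")
  J <- cross_integral(gs, es)
  # Phi (Phi'Phi)^-1 J through the QR of Phi: conditioned on kappa(Phi),
  # not kappa(Phi)^2 as the normal equations would be
  qrp <- qr(Phi)
  Rm <- qr.R(qrp)
  W <- qr.Q(qrp) %*% backsolve(Rm, J[qrp$pivot, , drop = FALSE],
                               transpose = TRUE)
  structure(list(W = W, Phi = Phi, Psi_eval = Psi, J = J,
                 effect_spec = es, genotype_spec = gs, notes = notes),
            class = "smoother")
}
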