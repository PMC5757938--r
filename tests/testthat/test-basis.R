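test_that("position scaling maps affinely to [0, 1] and preserves order", {
  expect_equal(scale_positions(c(100, 200, 300))$scaled, c(0, 0.5, 1))
  expect_equal(scale_positions(c(1000, 1001, 2000))$scaled, c(0, 0.001, 1))
  # unsorted input is sorted first
  pm <- scale_positions(c(300, 100, 200))
  expect_equal(pm$scaled, c(0, 0.5, 1))
  expect_equal(pm$order, c(2L, 3L, 1L))
})

test_that("degenerate and duplicated positions are handled deterministically", {
  expect_error(scale_positions(c(5, 5)), "degenerate")
  expect_error(scale_positions(7), "at least 2")
  pm1 <- scale_positions(c(100, 200, 200, 300))
  pm2 <- scale_positions(c(100, 200, 200, 300))
  expect_identical(pm1$scaled, pm2$scaled)
  expect_true(all(diff(pm1$scaled) > 0))      # duplicates separated
  expect_equal(pm1$scaled[c(1, 4)], c(0, 1))
  # jitter is tiny relative to the span
  expect_lt(pm1$scaled[3] - pm1$scaled[2], 1e-5)
})

test_that("Fourier basis rows match trigonometric values and K must be odd", {
  expect_equal(fourier_basis(0, 3)[1, ], c(1, 0, sqrt(2)))
  expect_equal(fourier_basis(0.25, 3)[1, ], c(1, sqrt(2), 0),
               tolerance = 1e-12)
  expect_error(fourier_basis(0.5, 4), "odd")
})

test_that("Fourier system is orthonormal on [0,1] (quadrature oracle)", {
  K <- 7
  J <- outer(seq_len(K), seq_len(K), Vectorize(function(i, j)
    stats::integrate(function(t) fourier_basis(t, K)[, i] *
                       fourier_basis(t, K)[, j],
                     0, 1, rel.tol = 1e-12)$value))
  expect_equal(J, diag(K), tolerance = 1e-10)
})

test_that("B-splines form a nonnegative partition of unity", {
  set.seed(1)
  t <- runif(1e4)
  for (K in c(4, 9, 15)) {
    B <- bspline_basis(t, K)
    expect_true(all(B >= 0))
    expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  }
  expect_error(bspline_basis(0.5, 3, order = 4), "K >= order")
})

test_that("K = order B-splines are Bernstein polynomials", {
  expect_equal(bspline_basis(0, 4, 4)[1, ], c(1, 0, 0, 0))
  expect_equal(bspline_basis(0.5, 4, 4)[1, ], c(0.125, 0.375, 0.375, 0.125))
  expect_equal(bspline_basis(1, 4, 4)[1, ], c(0, 0, 0, 1))
})

test_that("smoother matrix is composed exactly as Phi (Phi'Phi)^-1 J", {
  pm <- scale_positions(sort(sample.int(5000, 40)))
  gs <- basis_spec("bspline", 12)
  es <- basis_spec("fourier", 9)
  sm <- build_smoother(pm, gs, es)
  W_direct <- sm$Phi %*% solve(crossprod(sm$Phi)) %*% sm$J
  expect_equal(sm$W, W_direct, tolerance = 1e-12)
  expect_equal(dim(sm$W), c(40L, 9L))
})

test_that("beta-smooth-only smoother is the effect-basis evaluation matrix", {
  pm <- scale_positions(c(0, 500, 1000))
  sm <- build_smoother(pm, NULL, basis_spec("fourier", 3))
  expect_equal(sm$W, fourier_basis(c(0, 0.5, 1), 3))
})

test_that("identical Fourier bases give J = I and preserve the design space", {
  set.seed(2)
  pm <- scale_positions(sort(sample.int(9999, 30)))
  spec <- basis_spec("fourier", 11)
  sm <- build_smoother(pm, spec, spec)
  expect_equal(sm$J, diag(11), tolerance = 1e-10)
  G <- matrix(rbinom(20 * 30, 2, 0.3), 20, 30)
  # col space of G W equals col space of G Phi
  P1 <- qr.Q(qr(G %*% sm$W))
  M <- G %*% sm$Phi
  expect_lt(max(abs(M - P1 %*% crossprod(P1, M))), 1e-8)
})

test_that("quadrature cross-integral is exact for spline x spline products", {
  gs <- basis_spec("bspline", 8)
  es <- basis_spec("bspline", 6)
  J <- wflm:::cross_integral(gs, es)
  oracle <- outer(1:8, 1:6, Vectorize(function(i, j)
    stats::integrate(function(t) bspline_basis(t, 8)[, i] *
                       bspline_basis(t, 6)[, j],
                     0, 1, rel.tol = 1e-12, subdivisions = 400L)$value))
  expect_equal(J, oracle, tolerance = 1e-10)
})

test_that("oversized bases are reduced to the largest valid K <= m", {
  pm <- scale_positions(sort(sample.int(1000, 12)))
  sm <- build_smoother(pm, NULL, basis_spec("fourier", 25))
  expect_equal(sm$effect_spec$K, 11L)     # largest odd <= 12
  expect_match(sm$notes, "K_beta reduced", all = FALSE)
  sm2 <- build_smoother(pm, NULL, basis_spec("bspline", 15))
  expect_equal(sm2$effect_spec$K, 12L)
})
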