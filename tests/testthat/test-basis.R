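test_that("Fourier basis evaluates the constant + sin/cos pairs", {
  expect_equal(eval_fourier_basis(0, K = 3, domain_end = 10)[1, ],
               c(1, 0, 1))
  expect_equal(eval_fourier_basis(c(0, 3, 7), K = 1, domain_end = 10),
               matrix(1, 3, 1))
  # harmonic orthogonality by independent trapezoid quadrature
  grid <- seq(0, 10, length.out = 1001)
  Phi <- eval_fourier_basis(grid, K = 5, domain_end = 10)
  expect_lt(abs(trapz(grid, Phi[, 2] * Phi[, 3])), 1e-8)  # sin*cos, h = 1
  expect_lt(abs(trapz(grid, Phi[, 2] * Phi[, 4])), 1e-8)  # sin h=1 * sin h=2
  expect_error(eval_fourier_basis(0, K = 4, domain_end = 10),
               "adjust_n_basis")
  expect_error(eval_fourier_basis(11, K = 3, domain_end = 10), "domain")
})

test_that("B-spline basis is a clamped partition of unity matching Cox-de Boor", {
  set.seed(5)
  ts <- sort(runif(50, 0.01, 9.99))
  B <- eval_bspline_basis(ts, K = 6, domain_end = 10)
  expect_equal(rowSums(B), rep(1, 50), tolerance = 1e-12)
  expect_true(all(B >= -1e-12 & B <= 1 + 1e-12))
  expect_equal(eval_bspline_basis(0, K = 6, domain_end = 10)[1, ],
               c(1, 0, 0, 0, 0, 0))
  # independent Cox-de Boor recursion at interior points
  knots <- c(rep(0, 4), seq(0, 10, length.out = 4)[2:3], rep(10, 4))
  oracle <- t(vapply(ts, cox_de_boor_row, numeric(6L),
                     knots = knots, K = 6L, order = 4L))
  expect_equal(B, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(eval_bspline_basis(0, K = 3, domain_end = 10), "order")
})

test_that("roughness penalty matrices match closed forms and are PSD", {
  b <- basis_system("fourier", K = 3, domain_end = 2 * pi)
  R <- roughness_penalty_matrix(b)
  # omega = 1: second derivative of sin/cos has unit amplitude,
  # integral of sin^2 over a period is pi
  expect_equal(R, diag(c(0, pi, pi)), tolerance = 1e-12)
  expect_equal(R[1, ], rep(0, 3))

  bb <- basis_system("bspline", K = 7, domain_end = 10)
  Rb <- roughness_penalty_matrix(bb)
  expect_equal(Rb, t(Rb))
  expect_true(all(eigen(Rb, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
})

test_that("penalized smoothing reproduces constants, interpolates, and matches a direct solve", {
  # note t = 0 and t = T are the same point for the periodic Fourier
  # system, so a lambda = 0 design must not contain both
  ts <- c(0, 2, 5, 8, 9.5)
  for (b in list(basis_system("fourier", 5, 10),
                 basis_system("bspline", 5, 10))) {
    for (lam in c(0, 1e-2, 10)) {
      cv <- smooth_trajectory(ts, rep(5, 5), b, lambda = lam)
      expect_equal(eval_curve(cv, seq(0, 10, length.out = 31)),
                   rep(5, 31), tolerance = 1e-9)
    }
  }

  # saturated Fourier fit interpolates at lambda = 0
  set.seed(8)
  y <- rnorm(5, 10, 2)
  cv <- smooth_trajectory(ts, y, basis_system("fourier", 5, 10), lambda = 0)
  expect_equal(eval_curve(cv, ts), y, tolerance = 1e-8)

  # independent normal-equations solve for a linear signal
  ts10 <- seq(0, 10, length.out = 10)
  y10 <- 2 + 3 * ts10
  b5 <- basis_system("bspline", 5, 10)
  cv <- smooth_trajectory(ts10, y10, b5, lambda = 0)
  Phi <- eval_bspline_basis(ts10, 5, 10)
  coef_oracle <- qr.solve(Phi, y10)
  expect_equal(eval_curve(cv, ts10), drop(Phi %*% coef_oracle),
               tolerance = 1e-9)

  expect_error(smooth_trajectory(c(0, 1), c(1, 2),
                                 basis_system("fourier", 1, 10)),
               "3 observations")
  expect_error(smooth_trajectory(c(0, 0, 0, 1, 2), c(1, 1.2, 0.9, 2, 3),
                                 basis_system("fourier", 5, 10), lambda = 0),
               "lambda")
})

test_that("roughness decreases with lambda and the heavy-penalty limit is the null-space fit", {
  set.seed(21)
  ts <- seq(0, 10, length.out = 12)
  y <- sin(ts) + rnorm(12, 0, 0.3)

  for (fam in c("fourier", "bspline")) {
    b <- basis_system(fam, 7, 10)
    R <- roughness_penalty_matrix(b)
    rough <- vapply(c(0, 1e-4, 1e-2, 1, 100), function(lam) {
      cf <- smooth_trajectory(ts, y, b, lambda = lam)$coefficients
      drop(t(cf) %*% R %*% cf)
    }, numeric(1))
    expect_true(all(diff(rough) <= 1e-9))
  }

  # lambda -> Inf with p = 2: B-spline approaches the OLS straight line,
  # Fourier the best constant (only the constant is unpenalized)
  cv <- smooth_trajectory(ts, y, basis_system("bspline", 7, 10),
                          lambda = 1e8)
  ols <- lm.fit(cbind(1, ts), y)$coefficients
  expect_equal(eval_curve(cv, ts), drop(cbind(1, ts) %*% ols),
               tolerance = 1e-3)
  cv <- smooth_trajectory(ts, y, basis_system("fourier", 7, 10),
                          lambda = 1e8)
  expect_equal(eval_curve(cv, ts), rep(mean(y), 12), tolerance = 1e-3)
})

test_that("fitting is scale-equivariant and curves evaluate by direct summation", {
  set.seed(31)
  ts <- sort(runif(9, 0, 10))
  y <- rnorm(9, 5, 1)
  b <- basis_system("fourier", 5, 10)
  cv1 <- smooth_trajectory(ts, y, b, lambda = 0.1)
  cv2 <- smooth_trajectory(ts, 3 * y, b, lambda = 0.1)
  expect_equal(cv2$coefficients, 3 * cv1$coefficients, tolerance = 1e-10)

  grid <- seq(0, 10, length.out = 41)
  Phi <- eval_fourier_basis(grid, 5, 10)
  direct <- vapply(seq_along(grid), function(g)
    sum(cv1$coefficients * Phi[g, ]), numeric(1))
  expect_equal(eval_curve(cv1, grid), direct, tolerance = 1e-12)

  zero <- structure(list(coefficients = rep(0, 5), basis = b, lambda = 0),
                    class = "smoothed_curve")
  expect_equal(eval_curve(zero, grid), rep(0, 41))
})

test_that("GCV lambda selection picks a roughness level that tracks the noise", {
  set.seed(41)
  ts <- seq(0, 10, length.out = 20)
  y <- sin(0.6 * ts) + rnorm(20, 0, 0.4)
  cv <- smooth_trajectory(ts, y, basis_system("bspline", 12, 10),
                          lambda = "gcv")
  expect_true(cv$lambda > 1e-8)
  # the GCV fit must be smoother than the near-interpolant
  R <- roughness_penalty_matrix(basis_system("bspline", 12, 10))
  cf0 <- smooth_trajectory(ts, y, basis_system("bspline", 12, 10),
                           lambda = 1e-8)$coefficients
  cf1 <- cv$coefficients
  expect_lt(drop(t(cf1) %*% R %*% cf1), drop(t(cf0) %*% R %*% cf0) + 1e-9)
})
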