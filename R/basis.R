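#' Basis system for trajectory smoothing
#'
#' Defines the function system used to represent a subject-feature
#' trajectory: either Fourier harmonics (constant + sine/cosine pairs at
#' multiples of the fundamental frequency 2*pi/T) or clamped cubic
#' B-splines on a uniform knot grid over \code{[0, T]}.
#'
#' A Fourier system needs an odd number of functions (1 constant plus
#' whole sine/cosine pairs); even \code{K} is rejected — use
#' \code{\link{adjust_n_basis}} for the standard adjustment. A B-spline
#' system needs \code{K >= spline_order}.
#'
#' @param family \code{"fourier"} or \code{"bspline"}.
#' @param K number of basis functions.
#' @param domain_end domain upper end \code{T} (> 0).
#' @param spline_order B-spline order (default 4 = cubic).
#' @param penalty_order derivative order in the roughness penalty
#'   (default 2 = curvature).
#' @return an object of class \code{basis_system}.
#' @examples
#' b <- basis_system("fourier", K = 5, domain_end = 10)
#' Phi <- eval_basis(b, seq(0, 10, length.out = 21))
#' dim(Phi)
#' @export
basis_system <- function(family = c("fourier", "bspline"), K,
                         domain_end, spline_order = 4L,
                         penalty_order = 2L) {
  family <- match.arg(family)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (!is.numeric(domain_end) || domain_end <= 0) {
    stop("domain_end must be > 0", call. = FALSE)
  }
  if (family == "fourier" && K %% 2L == 0L) {
    stop("Fourier basis requires odd K (constant + sin/cos pairs); ",
         "use adjust_n_basis() to pick the nearest valid count",
         call. = FALSE)
  }
  if (family == "bspline" && K < spline_order) {
    stop(sprintf("B-spline basis requires K >= spline_order (%d)",
                 spline_order), call. = FALSE)
  }
  structure(list(family = family, K = K, domain_end = domain_end,
                 spline_order = as.integer(spline_order),
                 penalty_order = as.integer(penalty_order)),
            class = "basis_system")
}

#' @export
print.basis_system <- function(x, ...) {
  cat(sprintf("%s basis: K = %d on [0, %g]\n", x$family, x$K, x$domain_end))
  invisible(x)
}

#' Adjust a requested basis count to a valid one
#'
#' Implements the default sizing rule K = number of time points, with the
#' family-specific corrections: Fourier counts are rounded down to the
#' nearest odd value (a Fourier system is 1 + sin/cos pairs), and B-spline
#' counts are raised to the spline order when below it.
#'
#' @param K requested count.
#' @param family basis family.
#' @param spline_order B-spline order.
#' @return a valid basis count.
#' @export
adjust_n_basis <- function(K, family = c("fourier", "bspline"),
                           spline_order = 4L) {
  family <- match.arg(family)
  K <- as.integer(K)
  if (family == "fourier") {
    if (K %% 2L == 0L) K <- K - 1L
    K <- max(K, 1L)
  } else {
    K <- max(K, as.integer(spline_order))
  }
  K
}

#' Evaluate a Fourier basis
#'
#' Column 1 is the constant 1; columns 2h and 2h+1 are sin(h*w*t) and
#' cos(h*w*t) with w = 2*pi/T, for h = 1..(K-1)/2.
#'
#' @param times evaluation points in \code{[0, T]}.
#' @param K odd number of basis functions.
#' @param domain_end period \code{T}.
#' @return a \code{length(times) x K} matrix.
#' @export
eval_fourier_basis <- function(times, K, domain_end) {
  K <- as.integer(K)
  if (K %% 2L == 0L) {
    stop("Fourier basis requires odd K; use adjust_n_basis()", call. = FALSE)
  }
  check_in_domain(times, domain_end)
  Phi <- matrix(1, nrow = length(times), ncol = K)
  if (K > 1L) {
    omega <- 2 * pi / domain_end
    for (h in seq_len((K - 1L) %/% 2L)) {
      Phi[, 2L * h]      <- sin(h * omega * times)
      Phi[, 2L * h + 1L] <- cos(h * omega * times)
    }
  }
  Phi
}

#' Evaluate a clamped uniform B-spline basis
#'
#' Uses a clamped knot vector (order-fold boundary knots at 0 and T) with
#' \code{K - order} equally spaced interior knots, so the basis is a
#' partition of unity and interpolates at the endpoints.
#'
#' @param times evaluation points in \code{[0, T]}.
#' @param K number of basis functions, \code{>= order}.
#' @param domain_end domain upper end \code{T}.
#' @param order spline order (default 4 = cubic).
#' @param derivs derivative order to evaluate (default 0).
#' @return a \code{length(times) x K} matrix.
#' @export
eval_bspline_basis <- function(times, K, domain_end, order = 4L,
                               derivs = 0L) {
  K <- as.integer(K)
  order <- as.integer(order)
  if (K < order) {
    stop(sprintf("B-spline basis requires K >= order (%d)", order),
         call. = FALSE)
  }
  check_in_domain(times, domain_end)
  knots <- bspline_knots(K, domain_end, order)
  splines::splineDesign(knots, times, ord = order,
                        derivs = rep(as.integer(derivs), length(times)))
}

bspline_knots <- function(K, domain_end, order) {
  n_interior <- K - order
  interior <- if (n_interior > 0L) {
    seq(0, domain_end, length.out = n_interior + 2L)[seq(2L, n_interior + 1L)]
  } else numeric(0)
  c(rep(0, order), interior, rep(domain_end, order))
}

check_in_domain <- function(times, domain_end, tol = 1e-10) {
  if (any(times < -tol) || any(times > domain_end + tol)) {
    stop(sprintf("evaluation point outside domain [0, %g]", domain_end),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate a basis system
#'
#' @param basis a \code{\link{basis_system}}.
#' @param times evaluation points.
#' @export
eval_basis <- function(basis, times) {
  stopifnot(inherits(basis, "basis_system"))
  if (basis$family == "fourier") {
    eval_fourier_basis(times, basis$K, basis$domain_end)
  } else {
    eval_bspline_basis(times, basis$K, basis$domain_end,
                       order = basis$spline_order)
  }
}

#' Roughness penalty matrix
#'
#' R[a, b] = integral over \code{[0, T]} of the product of the p-th
#' derivatives of basis functions a and b. For the Fourier family this is
#' available in closed form (the system is orthogonal over a full period);
#' for B-splines it is computed by 1001-point trapezoid quadrature on the
#' derivative design matrix.
#'
#' @param basis a \code{\link{basis_system}}.
#' @param penalty_order derivative order p (defaults to the basis's own).
#' @return a symmetric positive semi-definite K x K matrix.
#' @export
roughness_penalty_matrix <- function(basis, penalty_order = NULL) {
  stopifnot(inherits(basis, "basis_system"))
  p <- if (is.null(penalty_order)) basis$penalty_order else as.integer(penalty_order)
  K <- basis$K
  T_end <- basis$domain_end
  if (basis$family == "fourier") {
    # p-th derivative of sin/cos at harmonic h has amplitude (h*omega)^p;
    # squared L2 norm over a full period is (h*omega)^(2p) * T/2
    d <- numeric(K)
    if (K > 1L) {
      omega <- 2 * pi / T_end
      for (h in seq_len((K - 1L) %/% 2L)) {
        val <- (h * omega)^(2 * p) * T_end / 2
        d[2L * h] <- val
        d[2L * h + 1L] <- val
      }
    }
    if (p == 0L) d[1L] <- T_end  # constant column only penalized at p = 0
    diag(d, nrow = K)
  } else {
    grid <- seq(0, T_end, length.out = 1001L)
    Dp <- eval_bspline_basis(grid, K, T_end, order = basis$spline_order,
                             derivs = p)
    w <- trapezoid_weights(grid)
    R <- crossprod(Dp, Dp * w)
    (R + t(R)) / 2
  }
}

trapezoid_weights <- function(grid) {
  G <- length(grid)
  h <- diff(grid)
  w <- numeric(G)
  w[1L] <- h[1L] / 2
  w[G] <- h[G - 1L] / 2
  if (G > 2L) w[2:(G - 1L)] <- (h[-1L] + h[-(G - 1L)]) / 2
  w
}

#' Smooth one trajectory by penalized least squares
#'
#' Fits coefficients c minimizing ||x - Phi c||^2 + lambda c' R c, where
#' Phi is the basis design at the observation times and R the roughness
#' penalty matrix. The fitted curve can then be evaluated anywhere on the
#' domain with \code{\link{eval_curve}}.
#'
#' @param times observation times (>= 3).
#' @param values observed abundances.
#' @param basis a \code{\link{basis_system}}.
#' @param lambda penalty weight (>= 0), or \code{"gcv"} to select it by
#'   generalized cross-validation over a log-spaced grid 1e-8..1e2.
#' @return an object of class \code{smoothed_curve} with elements
#'   \code{coefficients}, \code{basis}, \code{lambda}.
#' @export
smooth_trajectory <- function(times, values, basis, lambda = 1e-8) {
  stopifnot(inherits(basis, "basis_system"))
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("insufficient data: smoothing needs at least 3 observations",
         call. = FALSE)
  }
  check_in_domain(times, basis$domain_end)
  Phi <- eval_basis(basis, times)
  R <- roughness_penalty_matrix(basis)
  if (identical(lambda, "gcv")) {
    lambda <- select_lambda_gcv(Phi, values, R)
  }
  coef <- solve_penalized(Phi, values, R, lambda)
  structure(list(coefficients = coef, basis = basis, lambda = lambda),
            class = "smoothed_curve")
}

solve_penalized <- function(Phi, values, R, lambda) {
  A <- crossprod(Phi) + lambda * R
  b <- crossprod(Phi, values)
  coef <- tryCatch(solve(A, b),
                   error = function(e) {
                     stop("singular smoothing system (rank-deficient design, ",
                          "e.g. duplicate times at lambda = 0); ",
                          "use lambda > 0", call. = FALSE)
                   })
  drop(coef)
}

select_lambda_gcv <- function(Phi, values, R,
                              grid = 10^seq(-8, 2, length.out = 21)) {
  n <- length(values)
  PtP <- crossprod(Phi)
  scores <- vapply(grid, function(lam) {
    A <- PtP + lam * R
    H <- Phi %*% solve(A, t(Phi))
    fit <- drop(H %*% values)
    df <- sum(diag(H))
    rss <- sum((values - fit)^2)
    denom <- (1 - df / n)^2
    if (denom <= 0) Inf else rss / (n * denom)
  }, numeric(1L))
  grid[which.min(scores)]
}

#' Evaluate a smoothed curve
#'
#' @param curve a \code{smoothed_curve}.
#' @param grid evaluation points within the domain.
#' @return fitted values Phi(grid) c.
#' @export
eval_curve <- function(curve, grid) {
  stopifnot(inherits(curve, "smoothed_curve"))
  drop(eval_basis(curve$basis, grid) %*% curve$coefficients)
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat(sprintf("Smoothed curve: %s basis, K = %d, lambda = %g\n",
              x$basis$family, x$basis$K, x$lambda))
  invisible(x)
}
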