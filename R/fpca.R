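#' Functional principal component analysis for one feature
#'
#' Decomposes a sample of smoothed trajectories (one curve per subject,
#' all on a common domain) into a mean function, orthonormal
#' eigenfunctions, eigenvalues and per-subject scores. The decomposition
#' is computed on a discrete grid: curves are evaluated on \code{grid_size}
#' equally spaced points, the sample covariance (denominator n - 1) is
#' discretized with trapezoid quadrature weights, and a symmetric
#' eigendecomposition of the weighted covariance yields eigenpairs whose
#' eigenfunctions are orthonormal under the same quadrature. Scores are
#' the quadrature inner products of the centered curves with the
#' eigenfunctions.
#'
#' Sign convention: each eigenfunction is flipped so its integral over the
#' domain is nonnegative; when that integral is 0 (within 1e-12) the first
#' grid value is made nonnegative instead. This makes output deterministic.
#'
#' @param curves list of \code{smoothed_curve} objects sharing a domain
#'   (one per subject), optionally named by subject ID.
#' @param grid_size number of grid points (default 101, minimum 10).
#' @param n_components number of components R to retain: an integer or
#'   \code{"auto"} (smallest R with cumulative variance explained >=
#'   \code{var_threshold}, minimum 1).
#' @param var_threshold cumulative-variance threshold for \code{"auto"}
#'   (default 0.95).
#' @param feature_id optional feature label carried into the result.
#' @return an object of class \code{feature_fpca} with elements
#'   \code{grid}, \code{mean}, \code{eigenfunctions} (grid x R),
#'   \code{eigenvalues} (retained, non-increasing), \code{all_eigenvalues},
#'   \code{scores} (n x R), \code{n_components}, \code{subject_ids}.
#' @examples
#' b <- basis_system("fourier", K = 3, domain_end = 10)
#' curves <- lapply(c(-1, 0, 1), function(a)
#'   smooth_trajectory(seq(0, 10, length.out = 9),
#'                     a * sin(2 * pi * seq(0, 10, length.out = 9) / 10),
#'                     b, lambda = 0))
#' fp <- fit_fpca(curves)
#' variance_explained(fp)
#' @export
fit_fpca <- function(curves, grid_size = 101L, n_components = "auto",
                     var_threshold = 0.95, feature_id = NULL) {
  if (length(curves) < 2L) {
    stop("FPCA needs at least 2 subjects", call. = FALSE)
  }
  if (grid_size < 10L) {
    stop("grid_size must be at least 10", call. = FALSE)
  }
  T_end <- curves[[1L]]$basis$domain_end
  same <- vapply(curves, function(cv) isTRUE(all.equal(cv$basis$domain_end, T_end)),
                 logical(1L))
  if (!all(same)) stop("curves must share a common domain", call. = FALSE)
  grid <- seq(0, T_end, length.out = as.integer(grid_size))
  X <- vapply(curves, eval_curve, numeric(length(grid)), grid = grid)
  ids <- names(curves)
  if (is.null(ids)) ids <- paste0("S", seq_along(curves))
  fit_fpca_matrix(X, grid, n_components = n_components,
                  var_threshold = var_threshold, feature_id = feature_id,
                  subject_ids = ids)
}

# Core discretized FPCA on a G x n matrix of curve values on `grid`.
fit_fpca_matrix <- function(X, grid, n_components = "auto",
                            var_threshold = 0.95, feature_id = NULL,
                            subject_ids = colnames(X)) {
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  w <- trapezoid_weights(grid)
  sw <- sqrt(w)
  # weighted covariance: eigenproblem of W^(1/2) C W^(1/2), C = Xc Xc'/(n-1)
  Y <- (Xc * sw) / sqrt(n - 1)           # G x n
  if (n <= length(grid)) {
    # small-n route: eigen of the n x n Gram matrix (same nonzero spectrum)
    G <- crossprod(Y)
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    lam <- eg$values
    keep <- seq_len(min(n - 1L, length(lam)))
    U <- Y %*% eg$vectors
    nz <- lam > max(lam[1L], 0) * 1e-12
    U[, nz] <- sweep(U[, nz, drop = FALSE], 2L, sqrt(lam[nz]), "/")
    U[, !nz] <- 0
  } else {
    M <- tcrossprod(Y)
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    lam <- eg$values
    keep <- seq_len(min(n - 1L, length(lam)))
    U <- eg$vectors
  }
  lam <- lam[keep]
  U <- U[, keep, drop = FALSE]
  lam_max <- max(lam, 0)
  if (any(lam < -1e-10 * max(1, lam_max))) {
    stop("internal inconsistency: covariance eigenvalue substantially negative",
         call. = FALSE)
  }
  lam[lam < 0] <- 0
  psi <- U / sw                           # back-transform: orthonormal under quadrature
  # deterministic sign convention
  integrals <- colSums(psi * w)
  flip <- ifelse(abs(integrals) > 1e-12, sign(integrals),
                 ifelse(psi[1L, ] >= 0, 1, -1))
  flip[flip == 0] <- 1
  psi <- sweep(psi, 2L, flip, "*")
  total_var <- sum(lam)
  prop <- if (total_var > 0) lam / total_var else rep(0, length(lam))
  R <- resolve_n_components(n_components, prop, var_threshold)
  psi_R <- psi[, seq_len(R), drop = FALSE]
  scores <- crossprod(Xc * w, psi_R)      # n x R quadrature inner products
  rownames(scores) <- subject_ids
  structure(list(feature_id = feature_id,
                 grid = grid,
                 mean = mu,
                 eigenfunctions = psi_R,
                 eigenvalues = lam[seq_len(R)],
                 all_eigenvalues = lam,
                 scores = scores,
                 n_components = R,
                 subject_ids = subject_ids,
                 zero_variance = total_var <= 0),
            class = "feature_fpca")
}

resolve_n_components <- function(n_components, prop, var_threshold) {
  if (identical(n_components, "auto")) {
    if (all(prop == 0)) return(1L)
    cum <- cumsum(prop)
    max(1L, which(cum >= var_threshold - 1e-12)[1L])
  } else {
    R <- as.integer(n_components)
    if (R < 1L || R > length(prop)) {
      stop("n_components must be between 1 and the number of computed components",
           call. = FALSE)
    }
    R
  }
}

#' Fraction of variance explained by each component
#'
#' Returns the eigenvalue of each computed component divided by the total
#' over all computed components; the vector sums to 1 when any variance is
#' present. For a zero-variance feature an all-zero vector is returned
#' with a warning.
#'
#' @param fpca a \code{feature_fpca}.
#' @export
variance_explained <- function(fpca) {
  stopifnot(inherits(fpca, "feature_fpca"))
  total <- sum(fpca$all_eigenvalues)
  if (total <= 0) {
    warning("feature has zero variance; all components explain 0")
    return(rep(0, length(fpca$all_eigenvalues)))
  }
  fpca$all_eigenvalues / total
}

#' @export
print.feature_fpca <- function(x, ...) {
  ve <- if (x$zero_variance) rep(0, x$n_components) else
    (x$eigenvalues / sum(x$all_eigenvalues))
  cat(sprintf("FPCA%s: %d subjects, %d component(s), variance explained %s\n",
              if (is.null(x$feature_id)) "" else paste0(" [", x$feature_id, "]"),
              length(x$subject_ids), x$n_components,
              paste(sprintf("%.1f%%", 100 * ve), collapse = ", ")))
  invisible(x)
}
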