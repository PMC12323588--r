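# Independent oracles used across the suite. These re-derive expected
# values from first principles and must stay independent of the package
# internals they check.

# Textbook Cox-de Boor recursion for one B-spline basis function value.
cox_de_boor <- function(t, knots, i, order) {
  if (order == 1L) {
    return(as.numeric(knots[i] <= t && t < knots[i + 1L]))
  }
  left <- 0
  denom <- knots[i + order - 1L] - knots[i]
  if (denom > 0) {
    left <- (t - knots[i]) / denom * cox_de_boor(t, knots, i, order - 1L)
  }
  right <- 0
  denom <- knots[i + order] - knots[i + 1L]
  if (denom > 0) {
    right <- (knots[i + order] - t) / denom *
      cox_de_boor(t, knots, i + 1L, order - 1L)
  }
  left + right
}

cox_de_boor_row <- function(t, knots, K, order) {
  vapply(seq_len(K), function(i) cox_de_boor(t, knots, i, order), numeric(1L))
}

# Brute-force double loop over subject pairs for the eigenvalue-weighted
# score distance.
brute_force_feature_distance <- function(scores, eigenvalues) {
  n <- nrow(scores)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum(eigenvalues * (scores[i, ] - scores[j, ])^2))
    }
  }
  D
}

# Orthogonal Procrustes error: residual after optimally translating and
# rotating/reflecting X onto Y (no scaling).
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Yc, Xc))
  Q <- sv$v %*% t(sv$u)
  sqrt(sum((Xc %*% Q - Yc)^2))
}

# Exhaustive PERMANOVA: enumerate every assignment of n1 subjects to
# group A and compute the exact proportion of assignments with F >= F_obs.
permanova_f <- function(D, labels) {
  A <- D^2
  N <- nrow(D)
  groups <- unique(labels)
  SS_T <- sum(A) / (2 * N)
  SS_W <- 0
  for (g in groups) {
    idx <- which(labels == g)
    SS_W <- SS_W + sum(A[idx, idx]) / (2 * length(idx))
  }
  SS_A <- SS_T - SS_W
  if (SS_W <= 0) return(Inf)
  (SS_A / (length(groups) - 1)) / (SS_W / (N - length(groups)))
}

exhaustive_permanova_p <- function(D, labels) {
  n <- nrow(D)
  n1 <- sum(labels == labels[1L])
  F_obs <- permanova_f(D, labels)
  combos <- utils::combn(n, n1)
  f_all <- apply(combos, 2L, function(idx) {
    lab <- rep("B", n)
    lab[idx] <- "A"
    permanova_f(D, lab)
  })
  mean(f_all >= F_obs - 1e-12)
}

# Small toy longitudinal table builder.
toy_table <- function(subjects = c("S1", "S2", "S3"),
                      times = c(0, 1, 2, 3),
                      features = c("F1", "F2"),
                      value_fun = function(s, f, t) 1 + t,
                      groups = NULL) {
  obs <- expand.grid(subject = subjects, time = times, feature = features,
                     stringsAsFactors = FALSE)
  obs$value <- mapply(value_fun, obs$subject, obs$feature, obs$time)
  longitudinal_table(obs, groups = groups)
}

# Small simulated dataset for pipeline tests.
small_sim <- function(seed = 1, n_case = 5, n_control = 5, n_features = 8,
                      sparsity = 0, time_mode = "aligned") {
  simulate_dataset(sim_config(n_case = n_case, n_control = n_control,
                              n_features = n_features, sparsity = sparsity,
                              time_mode = time_mode, seed = seed))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# smoothed_curve built directly from Fourier coefficients (exact curves
# with known analytic form, bypassing the fitting step)
fourier_curve <- function(coefs, T_end = 10) {
  b <- basis_system("fourier", length(coefs), T_end)
  structure(list(coefficients = coefs, basis = b, lambda = 0),
            class = "smoothed_curve")
}
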