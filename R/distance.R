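#' Per-feature subject distance from an FPCA fit
#'
#' The distance between subjects i and i' on one feature is the
#' eigenvalue-weighted Euclidean distance between their FPCA score
#' vectors:
#' d(i, i') = sqrt( sum_r lambda_r (xi_ir - xi_i'r)^2 )
#' over the retained components r = 1..R, i.e. the ordinary Euclidean
#' distance between score vectors scaled componentwise by sqrt(lambda_r).
#'
#' @param fpca a \code{\link{fit_fpca}} result.
#' @return a symmetric n x n matrix with subject IDs as dimnames.
#' @export
feature_distance <- function(fpca) {
  stopifnot(inherits(fpca, "feature_fpca"))
  S <- fpca$scores %*% diag(sqrt(fpca$eigenvalues),
                            nrow = fpca$n_components)
  D <- as.matrix(stats::dist(S))
  dimnames(D) <- list(fpca$subject_ids, fpca$subject_ids)
  D
}

#' Aggregate per-feature distance matrices
#'
#' Combines feature-wise distances into one subject distance matrix by
#' root-sum-of-squares: D(i, i') = sqrt( sum_j d_j(i, i')^2 ).
#'
#' @param per_feature list of n x n distance matrices sharing subject IDs
#'   and order.
#' @param weights optional nonnegative per-feature weights applied to
#'   d_j^2 (default all 1).
#' @return a symmetric n x n matrix.
#' @export
aggregate_distances <- function(per_feature, weights = NULL) {
  if (length(per_feature) == 0L) stop("no distance matrices to aggregate",
                                      call. = FALSE)
  ids <- rownames(per_feature[[1L]])
  for (D in per_feature) {
    if (!identical(rownames(D), ids)) {
      stop("distance matrices have mismatched subject IDs or order",
           call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1, length(per_feature))
  if (length(weights) != length(per_feature) || any(weights < 0)) {
    stop("weights must be nonnegative, one per feature", call. = FALSE)
  }
  D2 <- 0
  for (j in seq_along(per_feature)) {
    D2 <- D2 + weights[j] * per_feature[[j]]^2
  }
  out <- sqrt(D2)
  dimnames(out) <- list(ids, ids)
  out
}

#' Longitudinal subject distances by smoothing + FPCA
#'
#' The end-to-end pipeline: every subject-feature trajectory is smoothed
#' by penalized basis-function least squares; per feature, FPCA across
#' subjects yields eigenvalues and subject scores; subjects are compared
#' per feature by the eigenvalue-weighted score distance; feature
#' distances are aggregated by root-sum-of-squares into the final
#' subject-by-subject matrix.
#'
#' A subject-feature series missing at some of the subject's sampled
#' times is completed with zeros (not detected = 0), so that every
#' feature's FPCA covers the identical subject set — a requirement of the
#' aggregation formula.
#'
#' The default basis size follows the rule K = number of the subject's
#' time points, adjusted per family (odd for Fourier, >= order for
#' B-splines) and never exceeding the number of observations.
#'
#' @param table a \code{\link{longitudinal_table}}; every subject must
#'   have at least 3 distinct times (apply
#'   \code{\link{require_min_timepoints}} first).
#' @param basis_family \code{"fourier"} (default) or \code{"bspline"}.
#' @param n_basis \code{"auto"} (the K = n_t rule) or an integer.
#' @param lambda smoothing penalty weight (default 1e-8) or \code{"gcv"}.
#' @param spline_order,penalty_order see \code{\link{basis_system}}.
#' @param grid_size FPCA evaluation grid size (default 101).
#' @param n_components FPCA components per feature: integer or
#'   \code{"auto"} (default).
#' @param var_threshold cumulative-variance threshold for \code{"auto"}.
#' @param weights optional per-feature aggregation weights (named by
#'   feature or in feature order).
#' @param keep_fpca keep the per-feature FPCA objects in the result
#'   (default TRUE; set FALSE in large replicate studies to save memory).
#' @return an object of class \code{lordist_fit}: list with
#'   \code{distance} (n x n matrix), \code{fpca} (list of
#'   \code{feature_fpca} or NULL), and \code{report} (per-feature
#'   components retained, variance explained, zero-variance flags).
#' @examples
#' sim <- simulate_dataset(sim_config(n_case = 5, n_control = 5,
#'                                    n_features = 10, seed = 1))
#' fit <- lordist(sim$table)
#' fit$distance[1:3, 1:3]
#' @export
lordist <- function(table,
                    basis_family = c("fourier", "bspline"),
                    n_basis = "auto",
                    lambda = 1e-8,
                    spline_order = 4L,
                    penalty_order = 2L,
                    grid_size = 101L,
                    n_components = "auto",
                    var_threshold = 0.95,
                    weights = NULL,
                    keep_fpca = TRUE) {
  stopifnot(inherits(table, "longitudinal_table"))
  basis_family <- match.arg(basis_family)
  subjects <- sort(unique(table$subject))
  features <- sort(unique(table$feature))
  n <- length(subjects)
  m <- length(features)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (m < 1L) stop("need at least 1 feature", call. = FALSE)
  T_end <- domain_end(table)
  grid <- seq(0, T_end, length.out = as.integer(grid_size))

  # per-subject sampling grid = union of that subject's observed times
  subj_times <- lapply(split(table$time, table$subject),
                       function(t) sort(unique(t)))
  subj_times <- subj_times[subjects]
  n_t <- vapply(subj_times, length, integer(1L))
  if (any(n_t < 3L)) {
    stop("subject(s) with fewer than 3 distinct time points: ",
         paste(subjects[n_t < 3L], collapse = ", "),
         "; apply require_min_timepoints() first", call. = FALSE)
  }

  # fill absent (subject, feature, time) records with 0 at the subject's
  # own sampled times: values[[i]] is an n_t[i] x m matrix
  si <- match(table$subject, subjects)
  fi <- match(table$feature, features)
  values <- vector("list", n)
  for (i in seq_len(n)) values[[i]] <- matrix(0, n_t[i], m)
  ti <- integer(nrow(table))
  for (i in seq_len(n)) {
    rows <- si == i
    ti[rows] <- match(table$time[rows], subj_times[[i]])
  }
  for (i in seq_len(n)) {
    rows <- which(si == i)
    values[[i]][cbind(ti[rows], fi[rows])] <- table$value[rows]
  }

  # smooth all of a subject's features in one penalized solve; subjects
  # sharing a time grid (and hence K) share the smoothing operator
  grid_key <- vapply(subj_times, function(t) paste(sprintf("%.12g", t),
                                                   collapse = ","),
                     character(1L))
  X_eval <- vector("list", n)
  for (key in unique(grid_key)) {
    idx <- which(grid_key == key)
    t_i <- subj_times[[idx[1L]]]
    K <- if (identical(n_basis, "auto")) length(t_i) else as.integer(n_basis)
    K <- min(adjust_n_basis(K, basis_family, spline_order), length(t_i))
    K <- adjust_n_basis(K, basis_family, spline_order)
    bs <- basis_system(basis_family, K, T_end,
                       spline_order = spline_order,
                       penalty_order = penalty_order)
    Phi <- eval_basis(bs, t_i)
    R <- roughness_penalty_matrix(bs)
    Phi_grid <- eval_basis(bs, grid)
    for (i in idx) {
      lam <- if (identical(lambda, "gcv")) {
        # one GCV selection per subject on the feature-averaged signal scale
        select_lambda_gcv(Phi, rowMeans(values[[i]]), R)
      } else lambda
      A <- crossprod(Phi) + lam * R
      coef <- tryCatch(solve(A, crossprod(Phi, values[[i]])),
                       error = function(e)
                         stop("singular smoothing system for subject ",
                              subjects[i], "; use lambda > 0", call. = FALSE))
      X_eval[[i]] <- Phi_grid %*% coef    # grid x m fitted values
    }
  }

  # per-feature FPCA and distance accumulation
  w_feat <- resolve_feature_weights(weights, features)
  D2 <- matrix(0, n, n)
  fpca_list <- if (keep_fpca) vector("list", m) else NULL
  report <- data.frame(feature = features,
                       n_components = integer(m),
                       variance_explained = numeric(m),
                       zero_variance = logical(m),
                       stringsAsFactors = FALSE)
  Xf <- matrix(0, length(grid), n)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) Xf[, i] <- X_eval[[i]][, j]
    colnames(Xf) <- subjects
    fp <- fit_fpca_matrix(Xf, grid, n_components = n_components,
                          var_threshold = var_threshold,
                          feature_id = features[j], subject_ids = subjects)
    S <- fp$scores %*% diag(sqrt(fp$eigenvalues), nrow = fp$n_components)
    sq <- rowSums(S^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(S)
    d2[d2 < 0] <- 0
    D2 <- D2 + w_feat[j] * d2
    tot <- sum(fp$all_eigenvalues)
    report$n_components[j] <- fp$n_components
    report$variance_explained[j] <-
      if (tot > 0) sum(fp$eigenvalues) / tot else 0
    report$zero_variance[j] <- fp$zero_variance
    if (keep_fpca) fpca_list[[j]] <- fp
  }
  D2 <- (D2 + t(D2)) / 2
  diag(D2) <- 0
  D <- sqrt(D2)
  dimnames(D) <- list(subjects, subjects)
  if (keep_fpca) names(fpca_list) <- features
  structure(list(distance = D, fpca = fpca_list, report = report,
                 config = list(basis_family = basis_family,
                               n_basis = n_basis, lambda = lambda,
                               spline_order = spline_order,
                               penalty_order = penalty_order,
                               grid_size = grid_size,
                               n_components = n_components,
                               var_threshold = var_threshold)),
            class = "lordist_fit")
}

resolve_feature_weights <- function(weights, features) {
  if (is.null(weights)) return(rep(1, length(features)))
  if (!is.null(names(weights))) {
    missing_w <- setdiff(features, names(weights))
    if (length(missing_w) > 0L) {
      stop("weights missing for feature(s): ",
           paste(missing_w, collapse = ", "), call. = FALSE)
    }
    weights <- weights[features]
  }
  if (length(weights) != length(features) || any(weights < 0)) {
    stop("weights must be nonnegative, one per feature", call. = FALSE)
  }
  as.numeric(weights)
}

#' @export
print.lordist_fit <- function(x, ...) {
  n <- nrow(x$distance)
  cat(sprintf("lordist fit: %d subjects, %d features (%s basis)\n",
              n, nrow(x$report), x$config$basis_family))
  cat(sprintf("  components retained: %s; zero-variance features: %d\n",
              paste(range(x$report$n_components), collapse = "-"),
              sum(x$report$zero_variance)))
  invisible(x)
}
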