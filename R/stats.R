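#' Principal coordinates analysis
#'
#' Classical multidimensional scaling: the squared-distance matrix is
#' double-centered (Gower), eigendecomposed, and coordinates for each
#' positive eigenvalue are the eigenvectors scaled by the square root of
#' that eigenvalue. Axes with non-positive eigenvalues are zero-filled.
#' Negative eigenvalues are reported, not corrected: distances produced
#' by \code{\link{lordist}} are Euclidean by construction, so their
#' negative eigenvalues are numerical noise only.
#'
#' @param D symmetric distance matrix (n >= 3).
#' @param k number of coordinate axes to return (default 2, at most
#'   n - 1).
#' @return an object of class \code{lordist_pcoa}: \code{coordinates}
#'   (n x k), \code{eigenvalues} (length n - 1, non-increasing),
#'   \code{all_eigenvalues} (length n), \code{negative_fraction}.
#' @export
pcoa <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("PCoA needs at least 3 subjects", call. = FALSE)
  k <- as.integer(k)
  if (k > n - 1L) stop("k must be at most n - 1", call. = FALSE)
  A <- D^2
  # Gower double centering: B = -1/2 J A J with J = I - 11'/n
  rm_ <- rowMeans(A)
  B <- -0.5 * (A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A))
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  ev <- eg$values
  coords <- matrix(0, n, k)
  tol <- 1e-9 * max(ev, 0)  # axes at numerical zero stay zero-filled
  for (a in seq_len(k)) {
    if (ev[a] > tol) coords[, a] <- eg$vectors[, a] * sqrt(ev[a])
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis.", seq_len(k))
  neg <- ev[ev < 0]
  structure(list(coordinates = coords,
                 eigenvalues = ev[seq_len(n - 1L)],
                 all_eigenvalues = ev,
                 negative_fraction = if (sum(abs(ev)) > 0)
                   sum(abs(neg)) / sum(abs(ev)) else 0),
            class = "lordist_pcoa")
}

#' @export
print.lordist_pcoa <- function(x, ...) {
  pos <- pmax(x$all_eigenvalues, 0)
  rel <- if (sum(pos) > 0) pos / sum(pos) else pos
  k <- ncol(x$coordinates)
  cat(sprintf("PCoA: %d subjects, %d axes (%s of positive inertia)\n",
              nrow(x$coordinates), k,
              paste(sprintf("%.1f%%", 100 * rel[seq_len(k)]),
                    collapse = " + ")))
  if (x$negative_fraction > 0) {
    cat(sprintf("  negative-eigenvalue fraction: %.2g\n",
                x$negative_fraction))
  }
  invisible(x)
}

#' PERMANOVA one-factor permutation test
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' partitions the total sum of squared distances into among-group and
#' within-group parts, forms the pseudo-F statistic
#' F = (SS_A / (a - 1)) / (SS_W / (N - a)), and obtains a p-value by
#' permuting group labels uniformly at random. The observed labeling is
#' counted once in both numerator and denominator, so
#' p = (1 + #\{F* >= F\}) / (1 + n_perm) and the smallest attainable
#' p-value is 1 / (1 + n_perm).
#'
#' When the within-group sum of squares is exactly 0 (all within-group
#' distances zero) F is reported as +Inf and the p-value still comes from
#' the permutation distribution.
#'
#' @param D symmetric distance matrix with subjects in rows/columns.
#' @param labels group labels aligned to the rows of D (character or
#'   factor, >= 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations (default 0); the global RNG
#'   state is restored afterwards.
#' @return an object of class \code{lordist_permanova}: \code{F},
#'   \code{p}, \code{n_perm}, \code{a} (groups), \code{N} (subjects),
#'   \code{seed}.
#' @export
permanova <- function(D, labels, n_perm = 999L, seed = 0L) {
  D <- as.matrix(D)
  N <- nrow(D)
  labels <- as.character(labels)
  if (length(labels) != N) {
    stop("labels must align with the distance matrix rows", call. = FALSE)
  }
  groups <- unique(labels)
  a <- length(groups)
  if (a < 2L) stop("PERMANOVA needs at least 2 groups", call. = FALSE)
  if (any(table(labels) < 1L)) stop("empty group", call. = FALSE)
  A <- D^2
  total_pair_sum <- sum(A) / 2          # sum over unordered pairs
  SS_T <- total_pair_sum / N
  f_stat <- function(lab) {
    SS_W <- 0
    for (g in groups) {
      idx <- which(lab == g)
      SS_W <- SS_W + sum(A[idx, idx]) / (2 * length(idx))
    }
    SS_A <- SS_T - SS_W
    if (SS_W <= 0) return(Inf)
    (SS_A / (a - 1)) / (SS_W / (N - a))
  }
  F_obs <- f_stat(labels)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (f_stat(sample(labels)) >= F_obs) count <- count + 1L
  }
  p <- (1 + count) / (1 + n_perm)
  structure(list(F = F_obs, p = p, n_perm = as.integer(n_perm),
                 a = a, N = N, seed = as.integer(seed)),
            class = "lordist_permanova")
}

#' @export
print.lordist_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.4g, p = %.4g (%d groups, %d subjects, %d permutations)\n",
              x$F, x$p, x$a, x$N, x$n_perm))
  invisible(x)
}
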