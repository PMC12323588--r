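# helper: minimal feature_fpca stub with given scores and eigenvalues
fpca_stub <- function(scores, eigenvalues) {
  structure(list(scores = scores, eigenvalues = eigenvalues,
                 all_eigenvalues = eigenvalues,
                 n_components = length(eigenvalues),
                 subject_ids = rownames(scores),
                 zero_variance = all(eigenvalues == 0)),
            class = "feature_fpca")
}

test_that("feature distance is the eigenvalue-weighted score distance", {
  scores <- matrix(c(1, 3), 2, 1, dimnames = list(c("S1", "S2"), NULL))
  D <- feature_distance(fpca_stub(scores, 4))
  expect_equal(D["S1", "S2"], 4)  # sqrt(4 * (1 - 3)^2)
  expect_equal(diag(D), c(S1 = 0, S2 = 0))

  set.seed(13)
  scores <- matrix(rnorm(8 * 3), 8, 3,
                   dimnames = list(paste0("S", 1:8), NULL))
  lam <- c(5, 2, 0.3)
  D <- feature_distance(fpca_stub(scores, lam))
  expect_equal(D, brute_force_feature_distance(scores, lam),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("aggregation is root-sum-of-squares across features", {
  ids <- c("S1", "S2")
  mk <- function(d) matrix(c(0, d, d, 0), 2, 2, dimnames = list(ids, ids))
  expect_equal(aggregate_distances(list(mk(3))), mk(3))
  expect_equal(aggregate_distances(list(mk(3), mk(4)))["S1", "S2"], 5)
  expect_equal(aggregate_distances(list(mk(0), mk(0))), mk(0))
  bad <- mk(1); rownames(bad) <- colnames(bad) <- c("S1", "X")
  expect_error(aggregate_distances(list(mk(1), bad)), "mismatched")
  # optional weights multiply squared distances
  expect_equal(aggregate_distances(list(mk(3), mk(4)),
                                   weights = c(1, 0))["S1", "S2"], 3)
})

test_that("the pipeline equals the operation-by-operation path on a small cohort", {
  sim <- small_sim(seed = 2, n_case = 4, n_control = 4, n_features = 5)
  tab <- sim$table
  fit <- lordist(tab, basis_family = "fourier", n_basis = 5,
                 lambda = 1e-8, n_components = "auto")
  subjects <- sort(unique(tab$subject))
  features <- sort(unique(tab$feature))
  b <- basis_system("fourier", 5, domain_end(tab))
  per_feature <- lapply(features, function(f) {
    curves <- lapply(subjects, function(s) {
      rows <- tab$subject == s & tab$feature == f
      smooth_trajectory(tab$time[rows], tab$value[rows], b, lambda = 1e-8)
    })
    names(curves) <- subjects
    feature_distance(fit_fpca(curves, n_components = "auto"))
  })
  D_manual <- aggregate_distances(per_feature)
  expect_equal(fit$distance, D_manual, tolerance = 1e-8)
})

test_that("degenerate and structured inputs behave as the formulas dictate", {
  # identical subjects -> zero distance matrix
  tab <- toy_table(subjects = paste0("S", 1:4), times = 0:4,
                   features = c("F1", "F2"),
                   value_fun = function(s, f, t) 3 + sin(t))
  fit <- lordist(tab)
  expect_true(all(fit$distance == 0))
  expect_true(all(fit$report$zero_variance))

  # duplicating every feature scales D by sqrt(2)
  sim <- small_sim(seed = 3, n_case = 3, n_control = 3, n_features = 4)
  tab <- sim$table
  dup <- as.data.frame(tab)
  dup$feature <- paste0(dup$feature, "dup")
  tab2 <- longitudinal_table(rbind(as.data.frame(tab), dup),
                             domain_end = domain_end(tab))
  D1 <- lordist(tab)$distance
  D2 <- lordist(tab2)$distance
  expect_equal(D2, sqrt(2) * D1, tolerance = 1e-8)

  # scaling one feature by c scales its feature distance by c^2
  b <- basis_system("fourier", 5, 10)
  set.seed(9)
  curves <- lapply(1:5, function(i) {
    structure(list(coefficients = rnorm(5), basis = b, lambda = 0),
              class = "smoothed_curve")
  })
  names(curves) <- paste0("S", 1:5)
  d1 <- feature_distance(fit_fpca(curves, n_components = 2))
  curves_sc <- lapply(curves, function(cv) {
    cv$coefficients <- 3 * cv$coefficients; cv
  })
  d2 <- feature_distance(fit_fpca(curves_sc, n_components = 2))
  expect_equal(d2, 9 * d1, tolerance = 1e-8)

  expect_error(lordist(toy_table(subjects = "S1")), "2 subjects")
})

test_that("aggregated distances satisfy metric axioms and embed in Euclidean space", {
  sim <- small_sim(seed = 6, n_case = 6, n_control = 6, n_features = 10,
                   sparsity = 0.3)
  D <- lordist(sim$table, keep_fpca = FALSE)$distance
  expect_equal(D, t(D), tolerance = 1e-9)
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  n <- nrow(D)
  set.seed(1)
  for (rep in 1:200) {
    ijk <- sample(n, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-8)
  }
  ev <- pcoa(D, k = 2)$all_eigenvalues
  expect_true(min(ev) >= -1e-6 * max(ev))
})

test_that("subject order does not affect the result and missing series are zero-filled", {
  sim <- small_sim(seed = 12, n_case = 3, n_control = 3, n_features = 4)
  tab <- sim$table
  shuffled <- as.data.frame(tab)[sample(nrow(tab)), ]
  tab2 <- longitudinal_table(shuffled, domain_end = domain_end(tab))
  expect_equal(lordist(tab)$distance, lordist(tab2)$distance,
               tolerance = 1e-10)

  # dropping one subject-feature series equals recording it as zeros
  drop_rows <- !(tab$subject == "case1" & tab$feature == "F1")
  tab_drop <- longitudinal_table(as.data.frame(tab)[drop_rows, ],
                                 domain_end = domain_end(tab))
  tab_zero <- as.data.frame(tab)
  tab_zero$value[!drop_rows] <- 0
  tab_zero <- longitudinal_table(tab_zero, domain_end = domain_end(tab))
  expect_equal(lordist(tab_drop)$distance, lordist(tab_zero)$distance,
               tolerance = 1e-10)
})
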