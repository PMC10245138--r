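test_that("PCA recovers a diagonal covariance exactly", {
  set.seed(20)
  n <- 4000
  X <- cbind(f1 = stats::rnorm(n, 0, 3), f2 = stats::rnorm(n, 0, 1))
  pr <- ff_pca(X, "raw")
  expect_equal(abs(pr$loadings[, 1]), c(f1 = 1, f2 = 0), tolerance = 0.02)
  expect_equal(pr$variance_explained, c(0.9, 0.1), tolerance = 0.02)
  expect_equal(sum(pr$variance_explained), 1)
  expect_true(all(diff(pr$eigenvalues) <= 1e-12))
  expect_equal(colMeans(pr$scores), rep(0, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scores and loadings reconstruct the (scaled) data", {
  set.seed(21)
  X <- matrix(stats::rnorm(40 * 7), 40, 7)
  for (sc in c("raw", "zscore")) {
    pr <- ff_pca(X, sc)
    Xs <- sweep(X, 2, pr$center)
    if (sc == "zscore") Xs <- sweep(Xs, 2, pr$sdev, "/")
    expect_equal(pr$scores %*% t(pr$loadings), Xs, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("PCA agrees with the SVD implementation path", {
  set.seed(22)
  X <- matrix(stats::rnorm(60 * 8), 60, 8)
  pr <- ff_pca(X, "zscore")
  ref <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(pr$eigenvalues, ref$sdev^2, tolerance = 1e-9)
  expect_equal(abs(pr$loadings), abs(ref$rotation), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("zscore PCA is invariant to affine rescaling of a feature", {
  set.seed(23)
  X <- matrix(stats::rnorm(50 * 6), 50, 6)
  X2 <- X
  X2[, 4] <- -250 + 1000 * X2[, 4]
  p1 <- ff_pca(X, "zscore")
  p2 <- ff_pca(X2, "zscore")
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8)
})

test_that("Kaiser retention applies the dual rule with ties retained", {
  pr <- structure(list(eigenvalues = c(3, 1.5, 0.9, 0.6), scale = "zscore"),
                  class = "ff_pca")
  expect_equal(kaiser_retain(pr), 1:2)
  pr_raw <- structure(list(eigenvalues = rep(2, 5), scale = "raw"),
                      class = "ff_pca")
  expect_equal(kaiser_retain(pr_raw), 1:5)
  expect_error(ff_pca(cbind(a = rep(1, 10), b = stats::rnorm(10)), "zscore"),
               "constant feature")
})

test_that("varimax rotation preserves orthogonality, communalities and block variance", {
  set.seed(24)
  ft <- simulate_feature_factors(n_per_group = 40, delta = 0, seed = 24)
  pr <- ff_pca(ft, "zscore")
  k <- length(kaiser_retain(pr))
  rot <- varimax_rotate(pr, k)
  L0 <- pr$loadings[, 1:k]
  L1 <- rot$loadings
  expect_equal(crossprod(L1), diag(k), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rowSums(L1^2), rowSums(L0^2), tolerance = 1e-9)
  expect_equal(sum(rot$eigenvalues), sum(pr$eigenvalues[1:k]),
               tolerance = 1e-9)
  # ascent of the varimax criterion
  crit <- function(L) sum(apply(L^2, 2, stats::var))
  expect_gte(crit(L1), crit(L0) - 1e-9)
  expect_error(varimax_rotate(pr, 1), "at least 2")
})

test_that("varimax is a fixed point on perfect simple structure", {
  # each feature loads on exactly one component, no zero rows
  L <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)) / sqrt(2)
  pr <- structure(list(loadings = L, eigenvalues = c(2, 1, 0.1, 0.1),
                       scores = matrix(stats::rnorm(20 * 2), 20, 2),
                       variance_explained = c(.5, .25, .15, .1),
                       scale = "raw", rotation = "none"),
                  class = "ff_pca")
  rot <- varimax_rotate(pr, 2)
  # rotation is identity up to sign/permutation
  expect_equal(abs(rot$rotmat), diag(2), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PC-score logistic classification finds thresholds and nulls", {
  set.seed(25)
  X <- matrix(stats::rnorm(40 * 5), 40, 5)
  X[21:40, 1] <- X[21:40, 1] + 30
  pr <- ff_pca(X, "raw")
  g <- rep(c("a", "b"), each = 20)
  cl <- fit_pc_classifier(pr, g, 1)
  expect_true(cl$separation)
  expect_equal(cl$accuracy, 1)
  s <- pr$scores[, 1]
  expect_true(cl$threshold > min(tapply(s, g, max)) &&
              cl$threshold < max(tapply(s, g, min)))
  expect_true(all(cl$probabilities >= 0 & cl$probabilities <= 1))

  # literally identical groups: coefficient 0, non-discriminative
  Xn <- rbind(X[1:20, ], X[1:20, ])
  prn <- ff_pca(Xn, "raw")
  cln <- fit_pc_classifier(prn, rep(c("a", "b"), each = 20), 1)
  expect_equal(unname(cln$coefficients[2]), 0, tolerance = 1e-6)
  expect_gt(cln$p_value, 0.99)

  # decision invariant to PC sign convention
  pr_flip <- pr
  pr_flip$scores[, 1] <- -pr_flip$scores[, 1]
  cl_flip <- fit_pc_classifier(pr_flip, g, 1)
  expect_equal(cl_flip$threshold, -cl$threshold, tolerance = 1e-6)
  expect_identical(cl_flip$predicted, cl$predicted)
})

test_that("PC1 classifier approaches the generating Bayes accuracy", {
  ft <- simulate_feature_factors(n_per_group = 30, delta = 3, seed = 26)
  pr <- ff_pca(ft, "zscore")
  cl <- fit_pc_classifier(pr, ft$group, 1)
  gt <- attr(ft, "ground_truth")
  # held-out evaluation on a large sample from the same generator
  te <- simulate_feature_factors(n_per_group = 1000, delta = 3, seed = 27)
  Xte <- feature_matrix(te)
  ste <- sweep(sweep(Xte, 2, pr$center), 2, pr$sdev, "/") %*%
    pr$loadings[, 1]
  prob <- stats::plogis(cl$coefficients[1] + cl$coefficients[2] * ste)
  acc <- mean(ifelse(prob > 0.5, "B", "A") == te$group)
  expect_lt(abs(acc - gt$bayes_accuracy), 0.05)
})
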