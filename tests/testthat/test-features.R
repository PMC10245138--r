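test_that("the default catalog yields exactly 39 finite measurements", {
  cat39 <- default_catalog()
  expect_equal(length(cat39$features), 39)
  tpl <- default_template()
  ds <- ff_dataset(tpl$mean_coords)
  ft <- compute_features(ds, cat39)
  X <- feature_matrix(ft)
  expect_equal(ncol(X), 39)
  expect_true(all(is.finite(X)))
  # unit sanity: angles in [0, 180], distances and areas non-negative
  u <- attr(ft, "units")
  expect_true(all(X[, u == "degrees"] >= 0 & X[, u == "degrees"] <= 180))
  expect_true(all(X[, u %in% c("length", "length2")] >= 0))
})

test_that("features are rigid-invariant and scale with similarity", {
  tpl <- default_template()
  cfg <- tpl$mean_coords
  ds <- ff_dataset(cfg)
  ft0 <- feature_matrix(compute_features(ds))
  u <- attr(compute_features(ds), "units")
  set.seed(3)
  moved <- apply_similarity(cfg, theta = 0.7, scale = 1, shift = c(42, -13))
  ft1 <- feature_matrix(compute_features(ff_dataset(moved)))
  expect_equal(ft1, ft0, tolerance = 1e-9)
  doubled <- apply_similarity(cfg, theta = 0, scale = 2)
  ft2 <- feature_matrix(compute_features(ff_dataset(doubled)))
  expect_equal(ft2[, u == "length"], 2 * ft0[, u == "length"],
               tolerance = 1e-9)
  expect_equal(ft2[, u == "length2"], 4 * ft0[, u == "length2"],
               tolerance = 1e-9)
  expect_equal(ft2[, u == "degrees"], ft0[, u == "degrees"],
               tolerance = 1e-9)
})

test_that("compute_features is pure and catalog errors are raised at load", {
  ds <- sim_three_groups(n = 3, seed = 12)
  expect_identical(compute_features(ds), compute_features(ds))
  expect_error(
    feature_catalog(list(list(name = "bad", kind = "distance",
                              landmarks = c(1, 99))),
                    schema = default_schema()),
    "outside 1..26")
  expect_error(
    feature_catalog(list(list(name = "c", kind = "composite", op = "sum",
                              inputs = list("nope"))),
                    schema = default_schema()),
    "undefined feature")
})

test_that("group comparison applies the Bonferroni threshold for 39 tests", {
  ds <- sim_three_groups(n = 10, seed = 13)
  gc <- compare_groups(compute_features(ds))
  expect_equal(gc$alpha_bonferroni_display, 0.00128)
  expect_equal(gc$alpha_bonferroni, 0.05 / 39)
  expect_identical(gc$table$significant, gc$table$p < 0.05 / 39)
})

test_that("identical groups give F = 0, p = 1 and no flags", {
  ds <- sim_three_groups(n = 4, seed = 14)
  ft <- compute_features(ds)
  # make the two groups literally identical copies
  X <- ft
  idx_wt <- which(ft$group == "WT")
  idx_het <- which(ft$group == "Het")
  fn <- attr(ft, "feature_names")
  X[idx_het, fn] <- X[idx_wt, fn]
  X <- X[c(idx_wt, idx_het), ]
  gc <- compare_groups(X)
  expect_lt(max(gc$table$F), 1e-10)
  expect_gt(min(gc$table$p), 1 - 1e-6)
  expect_false(any(gc$table$significant))
})

test_that("a 10-sigma shift in one feature is isolated by ANOVA and Tukey", {
  set.seed(15)
  n <- 30
  g <- rep(c("A", "B", "C"), each = n)
  X <- matrix(stats::rnorm(3 * n * 5), 3 * n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  X[g == "C", 3] <- X[g == "C", 3] + 10
  ft <- structure(cbind(data.frame(specimen_id = as.character(seq_along(g)),
                                   group = g), as.data.frame(X)),
                  feature_names = colnames(X),
                  units = rep("unitless", 5),
                  class = c("ff_features", "data.frame"))
  gc <- compare_groups(ft, alpha = 0.05)
  expect_identical(which(gc$table$significant), 3L)
  tk <- gc$tukey[["f3"]]
  expect_lt(tk["C-A", 1], 1e-6)
  expect_lt(tk["C-B", 1], 1e-6)
  expect_gt(tk["B-A", 1], 0.05)
  expect_error(compare_groups(ft[c(1, 31, 32, 61, 62), ]), "fewer than 2")
})

test_that("ANOVA and Tukey p-values agree with permutation oracles", {
  set.seed(16)
  y <- stats::rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  y[g == "c"] <- y[g == "c"] + 1.2
  ft <- structure(cbind(data.frame(specimen_id = as.character(1:15),
                                   group = g),
                        data.frame(f1 = y)),
                  feature_names = "f1", units = "unitless",
                  class = c("ff_features", "data.frame"))
  gc <- compare_groups(ft)
  p_perm <- perm_anova_p(y, g, B = 4000)
  expect_lt(abs(gc$table$p[1] - p_perm), 0.08)
  p_tk <- perm_tukey_p(y, g, B = 4000)
  tk <- gc$tukey[["f1"]][, 1]
  expect_lt(max(abs(tk[names(p_tk)] - p_tk)), 0.1)
})

test_that("compare_groups holds its familywise size on null data", {
  set.seed(17)
  n_rep <- 400
  rejections <- 0L
  tests <- 0L
  for (r in seq_len(n_rep)) {
    X <- matrix(stats::rnorm(30 * 3), 30, 3,
                dimnames = list(NULL, paste0("f", 1:3)))
    ft <- structure(cbind(data.frame(specimen_id = as.character(1:30),
                                     group = rep(c("A", "B", "C"), each = 10)),
                          as.data.frame(X)),
                    feature_names = colnames(X),
                    units = rep("unitless", 3),
                    class = c("ff_features", "data.frame"))
    gc <- compare_groups(ft, alpha = 0.05 * 3 / 39)  # threshold 0.05/39
    rejections <- rejections + sum(gc$table$significant)
    tests <- tests + 3L
  }
  rate <- rejections / tests
  thr <- 0.05 / 39
  expect_lte(rate, thr + 3 * sqrt(thr * (1 - thr) / tests))
})

test_that("length-to-width ratios behave and recover elongation", {
  co <- default_template()$mean_coords
  ds <- ff_dataset(co)
  # facial height (1-26) over facial width (10-11): 285 / 300
  r <- brain_length_width_ratio(ds, c(1, 26), c(10, 11))
  expect_equal(unname(r), 285 / 300)
  sq <- co; sq[1, ] <- c(0, 0); sq[26, ] <- c(0, 10)
  sq[10, ] <- c(-5, 5); sq[11, ] <- c(5, 5)
  expect_equal(unname(brain_length_width_ratio(ff_dataset(sq),
                                               c(1, 26), c(10, 11))), 1)
  bad <- co; bad[10, ] <- bad[11, ]
  expect_error(brain_length_width_ratio(ff_dataset(bad), c(1, 26), c(10, 11)),
               "zero width")
  # elongation factor recovery on simulated mutants
  ds2 <- simulate_dataset(data.frame(label = c("WT", "Mut"), n = c(40, 40),
                                     preset = c("none", "face_narrowing"),
                                     effect_scale = c(0, 1)),
                          seed = 18)
  r2 <- brain_length_width_ratio(ds2, c(1, 26), c(10, 11))
  g <- ds2$meta$group
  truth_wt <- 285 / 300
  mu <- attr(ds2, "ground_truth")$mean_shapes$Mut
  truth_mut <- lm_distance(mu[1, ], mu[26, ]) / lm_distance(mu[10, ], mu[11, ])
  expect_equal(mean(r2[g == "WT"]), truth_wt, tolerance = 0.02)
  expect_equal(mean(r2[g == "Mut"]), truth_mut, tolerance = 0.02)
  expect_gt(mean(r2[g == "Mut"]), mean(r2[g == "WT"]))
})
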