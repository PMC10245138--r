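test_that("shape PCA has exactly four null similarity dimensions", {
  ds <- simulate_dataset(data.frame(label = "A", n = 60), seed = 60)
  al <- gpa(ds)  # tangent projection on
  sp <- shape_pca(al)
  expect_equal(sum(sp$variance_explained), 1)
  lam <- sp$eigenvalues
  p <- ds$schema$n
  # 2p - 4 non-trivial dimensions; the 4 similarity directions are null
  expect_lt(lam[2 * p - 3] , 1e-12 * lam[1])
  expect_gt(lam[2 * p - 4], 1e-8 * lam[1])
  two <- subset_specimens(ds, 1:2)
  expect_error(shape_pca(gpa(two)), "at least 3")
})

test_that("shape PCA recovers a known deformation axis", {
  tpl <- default_template()
  v <- tpl$presets$mouth_elongation
  set.seed(61)
  n <- 50
  co <- array(NA_real_, c(26, 2, n))
  amp <- stats::rnorm(n, 0, 3)
  for (i in seq_len(n)) co[, , i] <- tpl$mean_coords + amp[i] * v
  al <- gpa(ff_dataset(co))
  sp <- shape_pca(al)
  expect_gt(sp$variance_explained[1], 0.999)
  # PC1 displacement field is parallel to the generating field (in the
  # tangent space, up to the similarity components GPA removes)
  d1 <- c(sp$displacements[, , 1])
  vt <- c(v) / sqrt(sum(v^2))
  expect_gt(abs(sum(d1 * vt)), 0.99)
})

test_that("CVA separates displaced groups and collapses identical ones", {
  ds <- sim_three_groups(n = 15, seed = 62, effect = 1)
  # make Het literally a copy of WT so their difference is exactly zero
  idx_wt <- which(ds$meta$group == "WT")
  idx_het <- which(ds$meta$group == "Het")
  ds$coords[, , idx_het] <- ds$coords[, , idx_wt]
  al <- gpa(ds)
  cv <- cva(al, n_perm = 199, seed = 63)
  d <- cv$procrustes
  expect_lt(d["WT", "Het"], 1e-6)
  expect_equal(cv$p_procrustes["WT", "Het"], 1)
  expect_gt(min(d["WT", "Mut"], d["Het", "Mut"]), d["WT", "Het"])
  expect_lt(cv$p_procrustes["WT", "Mut"], 0.05)
  expect_equal(dim(cv$scores), c(45L, 2L))
  expect_error(cva(al, groups = rep("one", 45)), "at least 2 groups")
})

test_that("CVA Mahalanobis approaches the analytic distance at large n", {
  tpl <- default_template()
  cs <- sqrt(sum(scale(tpl$mean_coords, scale = FALSE)^2))
  sig <- 1.5
  ds <- simulate_dataset(data.frame(label = c("A", "B"), n = c(150, 150),
                                    preset = c("none", "mutant"),
                                    effect_scale = c(0, 0.3)),
                         digitization_sd = sig, individual_sd = 0,
                         asymmetry_sd = 0, seed = 64)
  dstar <- attr(ds, "ground_truth")$procrustes["A", "B"]
  al <- gpa(ds)
  cv <- cva(al, n_perm = 49, seed = 65)
  expected <- dstar * cs / sig
  # undo the standard finite-sample inflation of the inverse-Wishart metric
  n <- 300; g <- 2; r <- cv$rank
  corrected <- cv$mahalanobis["A", "B"] * sqrt((n - g - r - 1) / (n - g))
  expect_equal(corrected, expected, tolerance = 0.1)
})

test_that("CVA permutation test holds its size under the null", {
  rej <- 0L
  n_rep <- 150
  for (r in seq_len(n_rep)) {
    ds <- simulate_dataset(data.frame(label = c("g1", "g2"), n = c(15, 15)),
                           seed = 6000 + r)
    cv <- cva(gpa(ds), n_perm = 99, seed = 7000 + r)
    rej <- rej + (cv$p_procrustes[1, 2] <= 0.05)
  }
  rate <- rej / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rate, 0.05 + 3 * se)
  expect_gte(rate, max(0, 0.05 - 3 * se))
})

test_that("DFA detects the mutant preset and reports exact-null p = 1", {
  ds <- sim_three_groups(n = 12, seed = 66)
  al <- gpa(ds)
  dd <- dfa(al, group_a = "WT", group_b = "Mut", n_perm = 999, seed = 67,
            loo = TRUE)
  expect_lt(dd$p_value, 0.01)
  expect_gt(dd$procrustes_distance, 0.02)
  expect_true(all(dim(dd$loo) == c(2, 2)))
  expect_gt(sum(diag(dd$loo)) / sum(dd$loo), 0.7)
  # identical groups: zero distance, p = 1
  ds2 <- ds
  idx_wt <- which(ds2$meta$group == "WT")
  idx_het <- which(ds2$meta$group == "Het")
  ds2$coords[, , idx_het] <- ds2$coords[, , idx_wt]
  dd0 <- dfa(gpa(ds2), group_a = "WT", group_b = "Het", n_perm = 199,
             seed = 68)
  expect_lt(dd0$procrustes_distance, 1e-6)
  expect_equal(dd0$p_value, 1)
  expect_error(dfa(al, group_a = "WT", group_b = "nope"), "not present")
})

test_that("permutation p resolution is 1/(n_perm + 1)", {
  ds <- simulate_dataset(data.frame(label = c("A", "B"), n = c(10, 10),
                                    preset = c("none", "mutant"),
                                    effect_scale = c(0, 3)),
                         digitization_sd = 0.5, seed = 69)
  dd <- dfa(gpa(ds), n_perm = 100, seed = 70)
  expect_equal(dd$p_value, 1 / 101)
})

test_that("the discriminant axis matches the lda cross-check", {
  skip_if_not_installed("MASS")
  ds <- simulate_dataset(data.frame(label = c("A", "B"), n = c(40, 40),
                                    preset = c("none", "mutant"),
                                    effect_scale = c(0, 1)),
                         seed = 71)
  al <- gpa(ds)
  red <- fishface:::reduce_shape_space(al, groups = ds$meta$group)
  # keep a low-dimensional, well-conditioned subspace for the comparison
  Y <- red$Y[, 1:10]
  g <- ds$meta$group
  W <- fishface:::pooled_within_cov(Y, factor(g))
  w_pkg <- drop(solve(W, colMeans(Y[g == "B", ]) - colMeans(Y[g == "A", ])))
  ld <- MASS::lda(Y, grouping = g)
  w_lda <- drop(ld$scaling)
  cosang <- abs(sum(w_pkg * w_lda)) /
    sqrt(sum(w_pkg^2) * sum(w_lda^2))
  expect_gt(cosang, 0.999)
})

test_that("wireframes superimpose, flip y, and show the mutant mouth change", {
  tpl <- default_template()
  ref <- tpl$mean_coords
  f <- withr::local_tempfile(fileext = ".svg")
  # identical shapes coincide
  out <- render_wireframe(wireframe(ref, ref), f)
  expect_true(file.exists(f))
  expect_equal(out$reference, out$target, tolerance = 1e-12)
  expect_equal(out$reference[, 2], -ref[, 2])  # y-flip
  # a scaled copy coincides after superimposition
  out2 <- render_wireframe(wireframe(ref, 2 * ref), f)
  expect_equal(out2$reference, out2$target, tolerance = 1e-9)
  # the mutant mean mouth is taller relative to the reference mouth
  mut <- ref + tpl$presets$mutant
  out3 <- render_wireframe(wireframe(ref, mut), f)
  mouth <- tpl$schema$mouth_indices
  h <- function(m) diff(range(m[mouth, 2]))
  w <- function(m) diff(range(m[mouth, 1]))
  expect_gt(h(out3$target) / w(out3$target),
            h(out3$reference) / w(out3$reference))
  expect_error(wireframe(ref, ref, edges = matrix(numeric(0), 0, 2)),
               "empty")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_wireframe(wireframe(ref, mut), f2)
  expect_true(file.size(f2) > 0)
})
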