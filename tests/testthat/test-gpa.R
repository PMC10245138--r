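test_that("GPA collapses the orbit of one shape under similarity transforms", {
  set.seed(30)
  base <- default_template()$mean_coords
  n <- 12
  co <- array(NA_real_, c(26, 2, n))
  for (i in seq_len(n))
    co[, , i] <- apply_similarity(base, stats::runif(1, 0, 2 * pi),
                                  stats::runif(1, 0.3, 3),
                                  stats::rnorm(2, 0, 200))
  al <- gpa(ff_dataset(co))
  spread <- max(abs(sweep(al$coords, c(1, 2), al$coords[, , 1])))
  expect_lt(spread, 1e-9)
  expect_lt(procrustes_distance(al$consensus, base), 1e-9)
})

test_that("aligned configurations are centred with unit centroid size", {
  ds <- sim_three_groups(n = 6, seed = 31)
  al <- gpa(ds, tangent = FALSE)
  for (i in seq_len(dim(al$coords)[3])) {
    cfg <- al$coords[, , i]
    expect_lt(max(abs(colMeans(cfg))), 1e-9)
    expect_equal(sqrt(sum(cfg^2)), 1, tolerance = 1e-9)
  }
  cons_mean <- apply(al$coords, c(1, 2), mean)
  cons_mean <- cons_mean / sqrt(sum(cons_mean^2))
  expect_lt(max(abs(cons_mean - al$consensus)), 1e-8)
  # with tangent projection the consensus is the plain mean
  alt <- gpa(ds, tangent = TRUE)
  expect_lt(max(abs(apply(alt$coords, c(1, 2), mean) - alt$consensus)), 1e-8)
  # original centroid sizes are preserved in original units
  z <- ds$coords[, , 2]
  expect_equal(unname(al$centroid_sizes[2]),
               sqrt(sum(sweep(z, 2, colMeans(z))^2)))
})

test_that("two-shape GPA equals the closed-form ordinary Procrustes distance", {
  set.seed(32)
  for (i in 1:100) {
    a <- rand_shape(15)
    b <- rand_shape(15)
    d_pkg <- procrustes_distance(a, b)
    d_oracle <- proc_dist_grid(a, b)
    expect_equal(d_pkg, d_oracle, tolerance = 1e-6)
    co <- array(NA_real_, c(15, 2, 2)); co[, , 1] <- a; co[, , 2] <- b
    al2 <- gpa(ff_dataset(co, schema = landmark_schema(
      data.frame(index = 1:15, name = paste0("p", 1:15), side = "midline"))),
      tangent = FALSE)
    d_gpa <- sqrt(sum((al2$coords[, , 1] - al2$coords[, , 2])^2))
    expect_equal(d_gpa, d_oracle, tolerance = 1e-6)
  }
})

test_that("procrustes_distance is a similarity-invariant metric", {
  set.seed(33)
  a <- rand_shape(26)
  moved <- apply_similarity(a, 37 * pi / 180, 3, c(11, -4))
  expect_lt(procrustes_distance(a, moved), 1e-12)
  b <- rand_shape(26)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
  expect_error(procrustes_distance(a, rand_shape(10)), "mismatch")
  # small-perturbation limit: distance grows linearly to first order
  ctr <- function(m) sweep(m, 2, colMeans(m))
  a0 <- ctr(a); a0 <- a0 / sqrt(sum(a0^2))
  v <- ctr(rand_shape(26)); v <- v - a0 * sum(v * a0); v <- v / sqrt(sum(v^2))
  eps <- 1e-5
  d <- procrustes_distance(a0, a0 + eps * v)
  expect_equal(d, eps, tolerance = 1e-3)
})

test_that("GPA is invariant to per-specimen similarity transforms of the input", {
  ds <- sim_three_groups(n = 5, seed = 34)
  al0 <- gpa(ds)
  set.seed(35)
  co <- ds$coords
  for (i in seq_len(dim(co)[3]))
    co[, , i] <- apply_similarity(co[, , i], stats::runif(1, 0, 2 * pi),
                                  stats::runif(1, 0.5, 2),
                                  stats::rnorm(2, 0, 100))
  al1 <- gpa(ff_dataset(co, meta = ds$meta))
  expect_lt(max(abs(al0$coords - al1$coords)), 1e-9)
  expect_error(gpa(ff_dataset(array(c(rep(1:26, 2), rep(1:26, 2)),
                                    c(26, 2, 2)),
                              schema = default_schema())),
               "degenerate")
})

test_that("procrustes_distance agrees with the vegan cross-check", {
  skip_if_not_installed("vegan")
  set.seed(36)
  a <- default_template()$mean_coords
  b <- a + matrix(stats::rnorm(52, 0, 4), 26, 2)
  ctr <- function(m) sweep(m, 2, colMeans(m))
  au <- ctr(a) / sqrt(sum(ctr(a)^2))
  bu <- ctr(b) / sqrt(sum(ctr(b)^2))
  ss <- vegan::procrustes(au, bu, symmetric = TRUE)$ss
  # vegan reports the full-Procrustes residual 1 - cos^2(rho); convert to
  # the partial (unit-size) distance sqrt(2 - 2 cos(rho))
  d_from_vegan <- sqrt(2 - 2 * sqrt(1 - ss))
  expect_equal(procrustes_distance(a, b), d_from_vegan, tolerance = 1e-9)
})
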